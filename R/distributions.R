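# Random-number kernels shared by the Gibbs samplers.  All use R's global
# RNG stream so entire chains are reproducible under set.seed().

#' Truncated standard-deviation-1 normal draws
#'
#' One draw per element of `mean`, truncated below at `lower` (or above at
#' `upper`).  Uses log-space inverse-CDF sampling, which stays accurate in
#' far tails (|mean - bound| > 6) where naive `qnorm(runif())` degenerates.
#'
#' @param mean vector of means.
#' @param lower,upper truncation bound (exactly one non-infinite; scalar or
#'   vector).
#' @return numeric vector of draws.
#' @export
rtnorm1 <- function(mean, lower = -Inf, upper = Inf) {
  n <- length(mean)
  if (all(is.infinite(lower)) && all(is.infinite(upper)))
    return(mean + stats::rnorm(n))
  if (any(is.finite(lower) & is.finite(upper)))
    stop("two-sided truncation not supported", call. = FALSE)
  out <- numeric(n)
  lo <- rep_len(lower, n); up <- rep_len(upper, n)
  below <- is.finite(lo)
  if (any(below)) {
    a <- lo[below] - mean[below]
    logp <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    u <- stats::runif(sum(below))
    out[below] <- mean[below] +
      stats::qnorm(log(u) + logp, lower.tail = FALSE, log.p = TRUE)
  }
  if (any(!below)) {
    b <- mean[!below] - up[!below]
    logp <- stats::pnorm(b, lower.tail = FALSE, log.p = TRUE)
    u <- stats::runif(sum(!below))
    out[!below] <- mean[!below] -
      stats::qnorm(log(u) + logp, lower.tail = FALSE, log.p = TRUE)
  }
  out
}

#' Scaled-inverse-chi-squared draws
#'
#' `df * scale / chisq(df)`; mean is `df * scale / (df - 2)` for df > 2.
#'
#' @param n number of draws.
#' @param df degrees of freedom (> 0).
#' @param scale scale parameter (> 0); may be a vector of length `n`.
#' @return numeric vector.
#' @export
rscinvchisq <- function(n, df, scale) {
  stopifnot(all(df > 0), all(scale > 0))
  df * scale / stats::rchisq(n, df)
}

#' Inverse-Gaussian draws
#'
#' Michael-Schucany-Haas transformation method; mean `mu`, shape `lambda`.
#'
#' @param n number of draws.
#' @param mu mean (> 0), scalar or length-n.
#' @param lambda shape (> 0).
#' @return numeric vector.
#' @export
rinvgauss <- function(n, mu, lambda) {
  mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  stopifnot(all(mu > 0), all(lambda > 0))
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  x <- pmax(x, .Machine$double.xmin)
  u <- stats::runif(n)
  flip <- u > mu / (mu + x)
  x[flip] <- mu[flip]^2 / x[flip]
  x
}
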
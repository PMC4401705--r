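# Single-site conditional updates of the probit whole-genome Gibbs
# sampler.  These are the reference implementations used directly for the
# latent-liability, fixed-effect and variance updates; the per-marker
# sweeps that dominate run time live in src/sweeps.cpp and implement the
# same conditionals.

#' Latent-liability update (probit data augmentation)
#'
#' Draws `z_i` from `N(eta_i, 1)` truncated to `(0, Inf)` when `y_i = 1`
#' and `(-Inf, 0]` when `y_i = 0` — the Albert-Chib augmentation of the
#' probit link with the threshold at 0 and residual variance fixed at 1.
#'
#' @param eta numeric vector of linear predictors.
#' @param y binary 0/1 vector.
#' @return numeric vector of liabilities; positive exactly where `y = 1`.
#' @export
update_latent_liability <- function(eta, y) {
  stopifnot(length(eta) == length(y), all(y %in% c(0, 1)),
            all(is.finite(eta)))
  z <- numeric(length(y))
  pos <- y == 1
  if (any(pos)) z[pos] <- rtnorm1(eta[pos], lower = 0)
  if (any(!pos)) z[!pos] <- rtnorm1(eta[!pos], upper = 0)
  z
}

#' Flat-prior fixed-effect update
#'
#' Joint draw of the fixed-effect coefficients from
#' `N((W'W)^{-1} W't, (W'W)^{-1})` where `t` is the current partial
#' residual (liability minus genetic part) and the residual variance is 1:
#' the conditional under a flat prior `p(alpha) proportional to 1`.
#'
#' @param W full-column-rank design matrix.
#' @param target partial residual vector the fixed effects regress on.
#' @param chol_WtW optional pre-computed `chol(crossprod(W))`.
#' @param alpha_bound divergence guard: a warning is raised when any
#'   coefficient draw exceeds this magnitude (quasi-separation symptom).
#' @return numeric coefficient vector.
#' @export
sample_fixed_effects <- function(W, target, chol_WtW = NULL,
                                 alpha_bound = Inf) {
  if (is.null(chol_WtW)) {
    qrW <- qr(W)
    if (qrW$rank < ncol(W)) {
      bad <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
      stop("fixed-effect design is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    chol_WtW <- chol(crossprod(W))
  }
  k <- ncol(W)
  mu <- backsolve(chol_WtW, backsolve(chol_WtW, crossprod(W, target),
                                      transpose = TRUE))
  draw <- drop(mu + backsolve(chol_WtW, stats::rnorm(k)))
  if (any(abs(draw) > alpha_bound))
    warning("fixed-effect draw exceeded |", alpha_bound,
            "|: possible quasi-separation", call. = FALSE)
  stats::setNames(draw, colnames(W))
}

#' Conditional marker-effect draw
#'
#' `beta_j ~ N(c_j / C_j, 1 / C_j)` with `C_j = x'x + 1/sigma2` and
#' `c_j = x' r`, `r` the partial residual excluding marker j.  A prior
#' variance at (numerical) zero returns exact zeros.
#'
#' @param x centered marker column.
#' @param resid partial residual excluding this marker's contribution.
#' @param sigma2 prior variance of the effect.
#' @param n_draws number of draws (> 1 only for Monte-Carlo checks).
#' @return numeric vector of draws.
#' @export
sample_marker_effect <- function(x, resid, sigma2, n_draws = 1L) {
  if (sigma2 <= 1e-300) return(rep(0, n_draws))
  C <- sum(x * x) + 1 / sigma2
  cc <- sum(x * resid)
  stats::rnorm(n_draws, cc / C, sqrt(1 / C))
}

#' Per-marker variance update (scaled-t / Bayes A prior)
#'
#' `sigma2_beta_j ~ scaled-inv-chisq(df + 1, (df*S + beta_j^2)/(df + 1))`.
#'
#' @param beta current marker effects.
#' @param df prior degrees of freedom (> 0).
#' @param S prior scale (> 0).
#' @return vector of variance draws, strictly positive.
#' @export
update_variance_bayes_a <- function(beta, df, S) {
  stopifnot(df > 0, S > 0)
  rscinvchisq(length(beta), df + 1, (df * S + beta^2) / (df + 1))
}

#' Null-mass probability update (spike-and-slab prior)
#'
#' `pi ~ Beta(a + n_null, b + n_included)` where `pi` is the prior mass of
#' the point at zero, following the mixture
#' `pi * 1(beta=0) + (1-pi) * N(0, sigma2_beta)`.
#'
#' @param n_null,n_included counts of excluded / included markers.
#' @param beta_prior Beta parameters `c(a, b)`.
#' @return one draw of `pi`.
#' @export
sample_pi <- function(n_null, n_included, beta_prior = c(1, 1)) {
  stopifnot(all(beta_prior > 0))
  stats::rbeta(1, beta_prior[1] + n_null, beta_prior[2] + n_included)
}

#' Slab-variance update (spike-and-slab prior)
#'
#' Scaled-inverse-chi-squared over the currently included effects.
#'
#' @param beta_included effects of included markers (possibly empty).
#' @param df,S prior degrees of freedom and scale.
#' @return one variance draw.
#' @export
sample_slab_variance <- function(beta_included, df, S) {
  m <- length(beta_included)
  rscinvchisq(1, df + m, (df * S + sum(beta_included^2)) / (df + m))
}

#' Bayesian-LASSO scale updates
#'
#' `1/tau2_j ~ inverse-Gaussian(sqrt(lambda2 / beta_j^2), lambda2)` and
#' `lambda2 ~ Gamma(shape + p, rate + sum(tau2)/2)`.  A `beta_j` of exactly
#' zero is guarded by drawing `tau2_j` from its exponential prior
#' `Exp(lambda2 / 2)`.
#'
#' @param beta current marker effects.
#' @param lambda2 current shrinkage parameter.
#' @param shape,rate gamma hyper-prior on `lambda2` (defaults 0.55 and
#'   0.0001).
#' @return list with `tau2` (vector) and `lambda2` (scalar).
#' @export
update_lasso_scales <- function(beta, lambda2, shape = 0.55, rate = 1e-4) {
  stopifnot(lambda2 > 0, shape > 0, rate > 0)
  p <- length(beta)
  tau2 <- numeric(p)
  nz <- abs(beta) > 1e-12
  if (any(nz))
    tau2[nz] <- 1 / rinvgauss(sum(nz), sqrt(lambda2 / beta[nz]^2), lambda2)
  if (any(!nz))
    tau2[!nz] <- stats::rexp(sum(!nz), rate = lambda2 / 2)
  lambda2_new <- stats::rgamma(1, shape + p, rate = rate + sum(tau2) / 2)
  list(tau2 = tau2, lambda2 = lambda2_new)
}

#' Genomic-value and variance update in the GRM eigenbasis
#'
#' With `G = E diag(lam) E'`, the genomic values are `u = E v` with
#' independent priors `v_k ~ N(0, lam_k * sigma2_u)`.  Given the residual
#' `r = z - W alpha` (residual variance 1), each `v_k` has a conjugate
#' normal conditional, and `sigma2_u` a scaled-inverse-chi-squared
#' conditional over the `n_eff` non-null eigenvalues (the pseudo-inverse
#' convention `u' G^- u = sum v_k^2 / lam_k`).
#'
#' @param r residual vector `z - W alpha`.
#' @param eig eigendecomposition of the GRM (`eigen(G, symmetric=TRUE)`).
#' @param sigma2_u current genomic variance.
#' @param df,S inverse-chi-squared prior degrees of freedom and scale.
#' @param tol eigenvalues below `tol * max(lam)` are treated as null.
#' @return list with `u`, `v`, `sigma2_u`.
#' @export
update_sigma_u <- function(r, eig, sigma2_u, df, S, tol = 1e-8) {
  lam <- eig$values
  if (min(lam) < -1e-6 * max(abs(lam)))
    stop("GRM is not positive semidefinite", call. = FALSE)
  keep <- lam > tol * max(lam)
  E <- eig$vectors[, keep, drop = FALSE]
  lam <- lam[keep]
  rt <- drop(crossprod(E, r))
  pv <- lam * sigma2_u / (1 + lam * sigma2_u)   # posterior variances
  v <- pv * rt + sqrt(pv) * stats::rnorm(length(lam))
  n_eff <- length(lam)
  sigma2_u_new <- rscinvchisq(1, df + n_eff,
                              (sum(v^2 / lam) + df * S) / (df + n_eff))
  list(u = drop(E %*% v), v = v, sigma2_u = sigma2_u_new)
}
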
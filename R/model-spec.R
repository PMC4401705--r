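#' Prior-family and hyperparameter specification
#'
#' Defines which prior the marker (or genomic) effects receive and every
#' hyperparameter of the Gibbs sampler.  Families:
#' \describe{
#'   \item{`fixed-only`}{no genetic term; covariates-only baseline.}
#'   \item{`bayes-a`}{per-marker variances under a scaled-inverse-chi-squared
#'     hyper-prior (marginally a scaled-t effect prior).}
#'   \item{`bayes-c-pi`}{spike-and-slab: point mass `pi` at zero plus a
#'     common-variance Gaussian slab, `pi` itself Beta-distributed.}
#'   \item{`b-lasso`}{double-exponential prior as a scale mixture of normals
#'     with exponential mixing and a gamma hyper-prior on `lambda2`.}
#'   \item{`gblup-brr`}{Bayesian ridge: one common marker-effect variance;
#'     equivalent to G-BLUP with the matched genomic relationship matrix.}
#'   \item{`gblup-grm`}{Gaussian genomic values with covariance
#'     `G * sigma2_u`, sampled in the eigenbasis of `G`.}
#' }
#'
#' Scale hyperparameters left `NULL` are resolved at fit time so the prior
#' mean of the genomic variance equals `R2/(1 - R2)` (residual liability
#' variance 1), partitioned by the markers' `sum 2q(1-q)` for marker-level
#' priors — the standard weakly-informative rule used by whole-genome
#' regression software.
#'
#' @param prior_family one of the families above.
#' @param link `"probit"` (binary outcome via latent liabilities) or
#'   `"identity"` (continuous outcome; validation runs).
#' @param df_beta,S_beta marker-variance prior df and scale (bayes-a, the
#'   slab, b-lasso init, brr).
#' @param pi_prior spike-and-slab Beta prior as `c(prob, counts)`: prior
#'   probability that a marker is null and prior weight in pseudo-counts.
#' @param lasso_shape,lasso_rate gamma hyper-prior on `lambda2`.
#' @param df_u,S_u genomic-variance prior df and scale (gblup-grm).
#' @param R2 prior proportion of liability variance attributed to markers,
#'   used only to resolve `NULL` scales.
#' @param fixed_variances if TRUE no variance parameter is updated
#'   (conjugate-validation mode; requires explicit scales).
#' @param sigma2_beta_fixed common marker-effect variance used when
#'   `fixed_variances = TRUE`.
#' @param alpha_bound divergence guard on fixed-effect draws.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(prior_family = c("gblup-brr", "bayes-a", "bayes-c-pi",
                                        "b-lasso", "gblup-grm", "fixed-only"),
                       link = c("probit", "identity"),
                       df_beta = 5, S_beta = NULL,
                       pi_prior = c(prob = 0.5, counts = 10),
                       lasso_shape = 0.55, lasso_rate = 1e-4,
                       df_u = 5, S_u = NULL, R2 = 0.5,
                       fixed_variances = FALSE, sigma2_beta_fixed = NULL,
                       alpha_bound = 25) {
  prior_family <- match.arg(prior_family)
  link <- match.arg(link)
  stopifnot(df_beta > 0, df_u > 0, lasso_shape > 0, lasso_rate > 0,
            R2 > 0, R2 < 1, length(pi_prior) == 2)
  if (pi_prior[1] < 0 || pi_prior[1] > 1 || pi_prior[2] <= 0)
    stop("pi_prior is c(prob in [0,1], counts > 0)", call. = FALSE)
  if (!is.null(S_beta) && S_beta <= 0) stop("S_beta must be > 0",
                                            call. = FALSE)
  if (!is.null(S_u) && S_u <= 0) stop("S_u must be > 0", call. = FALSE)
  if (fixed_variances && is.null(sigma2_beta_fixed) &&
      prior_family != "fixed-only")
    stop("fixed_variances requires sigma2_beta_fixed", call. = FALSE)
  structure(list(prior_family = prior_family, link = link,
                 df_beta = df_beta, S_beta = S_beta,
                 pi_prior = stats::setNames(as.numeric(pi_prior),
                                            c("prob", "counts")),
                 lasso_shape = lasso_shape, lasso_rate = lasso_rate,
                 df_u = df_u, S_u = S_u, R2 = R2,
                 fixed_variances = fixed_variances,
                 sigma2_beta_fixed = sigma2_beta_fixed,
                 alpha_bound = alpha_bound),
            class = "model_spec")
}

#' MCMC run configuration
#'
#' Defaults follow the long-chain convention of whole-genome regression
#' analyses: 40,000 iterations with 15,000 discarded as burn-in; thinning
#' by 5 keeps sample storage modest.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before summarization (< n_iter).
#' @param thin keep every `thin`-th post-burn-in iteration (>= 1).
#' @param seed integer RNG seed.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 40000L, burn_in = 15000L, thin = 5L,
                        seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  if (burn_in < 0 || thin < 1L) stop("burn_in >= 0 and thin >= 1",
                                     call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)), class = "mcmc_config")
}
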
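#' Fit a probit-link whole-genome regression by Gibbs sampling
#'
#' Bayesian regression of a binary outcome on non-genetic covariates (flat
#' prior) plus a genetic term, on the liability scale: `P(y=1) = Phi(eta)`
#' with `eta = W alpha + u` and residual liability variance fixed at 1.
#' The binary outcome is handled by truncated-normal data augmentation
#' (threshold at 0).  The genetic term is either a regression on centered
#' marker dosages (`u = X_c beta`, priors per [model_spec()]) or a Gaussian
#' genomic value with GRM covariance (`gblup-grm`).
#'
#' Each Gibbs cycle updates: latent liabilities, fixed effects, marker (or
#' genomic) effects via the compiled sweep, then the prior-specific
#' variance parameters.  The genomic variance trace is transformed to
#' liability-scale heritability `h2 = sigma2_u / (sigma2_u + 1)` per
#' sample.
#'
#' @param y binary 0/1 outcome (both classes required) for the probit
#'   link, or a continuous response for `link = "identity"` validation
#'   runs.
#' @param fixed_design numeric matrix of covariates including an intercept
#'   column; must be full column rank.
#' @param genetic_part `NULL` (fixed-only), a dosage matrix /
#'   `genotype_matrix` (marker families), or a `grm` (gblup-grm).
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_config()].
#' @return object of class `wgr_fit`: posterior means/SDs of `alpha` and
#'   `beta`, per-subject `eta_hat` and `prob_hat`, the `h2_estimate`,
#'   full traces of scalar parameters with Geweke stationarity z-scores,
#'   and the metadata needed for out-of-sample prediction.
#' @export
fit_probit_wgr <- function(y, fixed_design, genetic_part = NULL,
                           spec = model_spec(), mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  n <- length(y)
  probit <- spec$link == "probit"
  if (probit) {
    if (!all(y %in% c(0, 1)))
      stop("probit link requires a 0/1 outcome", call. = FALSE)
    if (length(unique(y)) < 2L)
      stop("outcome has a single class", call. = FALSE)
  }
  W <- as.matrix(fixed_design)
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  stopifnot(nrow(W) == n)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chol_WtW <- chol(crossprod(W))
  k <- ncol(W)
  fam <- spec$prior_family
  marker_fam <- fam %in% c("bayes-a", "bayes-c-pi", "b-lasso", "gblup-brr")

  Xc <- NULL; q <- NULL; sum2pq <- NA_real_; eig <- NULL
  mids <- NULL; p <- 0L
  if (marker_fam) {
    if (is.null(genetic_part))
      stop("prior family '", fam, "' needs a marker matrix", call. = FALSE)
    X <- if (inherits(genetic_part, "genotype_matrix"))
      unclass_dosages(genetic_part) else as.matrix(genetic_part)
    if (anyNA(X)) stop("marker matrix must be complete (impute first)",
                       call. = FALSE)
    stopifnot(nrow(X) == n)
    mids <- colnames(X)
    p <- ncol(X)
    # markers are always centered at 2 q_hat (= the column mean), which
    # the GRM/ridge equivalence requires
    q <- colMeans(X) / 2
    Xc <- sweep(X, 2L, 2 * q)
    # variance partition: empirical sum of centered second moments, the
    # shift-invariant estimator of 2 sum q(1-q) under Hardy-Weinberg
    sum2pq <- sum(colMeans(Xc^2))
    if (sum2pq <= 0) stop("all markers monomorphic", call. = FALSE)
    xtx <- colSums(Xc^2)
  } else if (fam == "gblup-grm") {
    if (is.null(genetic_part))
      stop("gblup-grm needs a GRM", call. = FALSE)
    Gm <- unclass(genetic_part)
    attributes(Gm) <- list(dim = dim(Gm), dimnames = dimnames(Gm))
    stopifnot(nrow(Gm) == n, ncol(Gm) == n)
    eig <- eigen(Gm, symmetric = TRUE)
    if (min(eig$values) < -1e-6 * max(abs(eig$values)))
      stop("GRM is not positive semidefinite", call. = FALSE)
  }

  # ---- resolve hyperparameter scales (prior mean of genomic variance
  #      = R2/(1-R2), residual liability variance 1) ----
  V <- spec$R2 / (1 - spec$R2)
  dfb <- spec$df_beta; dfu <- spec$df_u
  S_u <- spec$S_u
  if (is.null(S_u)) S_u <- if (dfu > 2) V * (dfu - 2) / dfu else V
  S_beta <- spec$S_beta
  if (is.null(S_beta) && marker_fam) {
    S_beta <- if (dfb > 2) V / sum2pq * (dfb - 2) / dfb else V / sum2pq
    if (fam == "bayes-c-pi")
      S_beta <- S_beta / max(1 - spec$pi_prior[["prob"]], 0.01)
  }
  if (fam == "bayes-a" && dfb < 4)
    warning("Bayes A with df_beta < 4 is prone to poor mixing; ",
            "df_beta >= 4 recommended", call. = FALSE)

  set.seed(mcmc$seed)
  # ---- state ----
  alpha <- numeric(k)
  z <- if (probit) update_latent_liability(numeric(n), y) else as.numeric(y)
  beta <- numeric(p)
  u <- numeric(n)
  sigma2_beta <- if (spec$fixed_variances) spec$sigma2_beta_fixed
                 else if (marker_fam) S_beta * dfb / max(dfb - 2, 1) else NA
  sigma2_beta_j <- rep(if (marker_fam) sigma2_beta else 0, p)  # bayes-a
  tau2 <- rep(if (marker_fam) sigma2_beta else 0, p)           # b-lasso
  lambda2 <- if (marker_fam) 2 * sum2pq / V else NA
  pi_null <- spec$pi_prior[["prob"]]
  pi_ab <- c(spec$pi_prior[["prob"]] * spec$pi_prior[["counts"]],
             (1 - spec$pi_prior[["prob"]]) * spec$pi_prior[["counts"]])
  delta <- integer(p)
  sigma2_u <- V
  resid <- z - drop(W %*% alpha) - u

  # ---- storage ----
  extra <- switch(fam,
                  "bayes-c-pi" = c("sigma2_beta", "pi"),
                  "gblup-brr" = "sigma2_beta",
                  "b-lasso" = "lambda2",
                  character(0))
  trace <- matrix(NA_real_, mcmc$n_iter, k + 1L + length(extra),
                  dimnames = list(NULL, c(colnames(W), "sigma2_u", extra)))
  retained <- seq.int(mcmc$burn_in + 1L, mcmc$n_iter, by = mcmc$thin)
  beta_sum <- numeric(p); beta_sq <- numeric(p)
  u_sum <- numeric(n); eta_sum <- numeric(n)
  n_ret <- 0L
  warned_alpha <- FALSE

  for (t in seq_len(mcmc$n_iter)) {
    # 1. latent liabilities
    if (probit) {
      eta <- z - resid
      z_new <- update_latent_liability(eta, y)
      resid <- resid + (z_new - z)
      z <- z_new
    }
    # 2. fixed effects (flat prior)
    Wa <- drop(W %*% alpha)
    target <- Wa + resid                    # z - u
    alpha <- withCallingHandlers(
      sample_fixed_effects(W, target, chol_WtW,
                           alpha_bound = spec$alpha_bound),
      warning = function(w) {
        if (!warned_alpha) warned_alpha <<- TRUE else
          invokeRestart("muffleWarning")
      })
    Wa <- drop(W %*% alpha)
    resid <- target - Wa
    # 3. genetic effects + variances
    if (fam == "gblup-brr") {
      sweep_normal(Xc, resid, beta, rep(sigma2_beta, p), xtx)
      if (!spec$fixed_variances)
        sigma2_beta <- rscinvchisq(
          1, dfb + p, (dfb * S_beta + sum(beta^2)) / (dfb + p))
      sigma2_u <- sigma2_beta * sum2pq
    } else if (fam == "bayes-a") {
      sweep_normal(Xc, resid, beta, sigma2_beta_j, xtx)
      if (!spec$fixed_variances)
        sigma2_beta_j <- update_variance_bayes_a(beta, dfb, S_beta)
      sigma2_u <- stats::var(z - Wa - resid)
    } else if (fam == "bayes-c-pi") {
      n_in <- sweep_mixture(Xc, resid, beta, delta, sigma2_beta, pi_null,
                            xtx)
      if (!spec$fixed_variances) {
        pi_null <- sample_pi(p - n_in, n_in, pi_ab)
        sigma2_beta <- sample_slab_variance(beta[delta == 1L], dfb, S_beta)
      }
      sigma2_u <- stats::var(z - Wa - resid)
    } else if (fam == "b-lasso") {
      sweep_normal(Xc, resid, beta, tau2, xtx)
      if (!spec$fixed_variances) {
        ls <- update_lasso_scales(beta, lambda2, spec$lasso_shape,
                                  spec$lasso_rate)
        tau2 <- ls$tau2; lambda2 <- ls$lambda2
      }
      sigma2_u <- stats::var(z - Wa - resid)
    } else if (fam == "gblup-grm") {
      r <- resid + u                        # z - W alpha
      upd <- update_sigma_u(r, eig, sigma2_u, dfu, S_u)
      u <- upd$u
      if (!spec$fixed_variances) sigma2_u <- upd$sigma2_u
      resid <- r - u
    } else {                                # fixed-only
      sigma2_u <- 0
    }
    # 4. record
    trace[t, seq_len(k)] <- alpha
    trace[t, k + 1L] <- sigma2_u
    if (fam == "bayes-c-pi") {
      trace[t, "sigma2_beta"] <- sigma2_beta
      trace[t, "pi"] <- pi_null
    } else if (fam == "gblup-brr") {
      trace[t, "sigma2_beta"] <- sigma2_beta
    } else if (fam == "b-lasso") {
      trace[t, "lambda2"] <- lambda2
    }
    if (t > mcmc$burn_in && (t - mcmc$burn_in - 1L) %% mcmc$thin == 0L) {
      n_ret <- n_ret + 1L
      if (p > 0L) { beta_sum <- beta_sum + beta; beta_sq <- beta_sq + beta^2 }
      u_now <- if (marker_fam) z - Wa - resid else u
      u_sum <- u_sum + u_now
      eta_sum <- eta_sum + Wa + u_now
    }
  }

  summ <- posterior_summary(trace, mcmc)
  alpha_hat <- summ$mean[seq_len(k)]
  beta_hat <- if (p > 0L) beta_sum / n_ret else numeric(0)
  beta_sd <- if (p > 0L)
    sqrt(pmax(beta_sq / n_ret - beta_hat^2, 0)) else numeric(0)
  names(beta_hat) <- mids; names(beta_sd) <- mids
  eta_hat <- eta_sum / n_ret
  h2 <- if (fam == "fixed-only") NULL else
    heritability(trace[retained, "sigma2_u"])

  structure(list(
    prior_family = fam, spec = spec, mcmc = mcmc,
    alpha = list(mean = alpha_hat, sd = summ$sd[seq_len(k)],
                 samples = trace[retained, seq_len(k), drop = FALSE]),
    beta = list(mean = beta_hat, sd = beta_sd),
    u_hat = u_sum / n_ret,
    eta_hat = eta_hat,
    prob_hat = stats::pnorm(eta_hat),
    h2 = h2,
    pi = if (fam == "bayes-c-pi") list(
      samples = trace[retained, "pi"],
      nonnull = list(samples = 1 - trace[retained, "pi"],
                     mean = mean(1 - trace[retained, "pi"]),
                     sd = stats::sd(1 - trace[retained, "pi"]))) else NULL,
    summary = summ,
    center_freq = q, sum2pq = sum2pq,
    fixed_names = colnames(W)), class = "wgr_fit")
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("wgr_fit: %s (%s link), %d iterations (%d burn-in, thin %d)\n",
              x$prior_family, x$spec$link, x$mcmc$n_iter, x$mcmc$burn_in,
              x$mcmc$thin))
  cat("fixed effects (posterior mean +/- SD):\n")
  print(round(cbind(mean = x$alpha$mean, sd = x$alpha$sd), 4))
  if (!is.null(x$h2))
    cat(sprintf("genomic variance %.3f +/- %.3f; h2 %.3f +/- %.3f\n",
                x$h2$sigma_u2$mean, x$h2$sigma_u2$sd,
                x$h2$h2$mean, x$h2$h2$sd))
  if (!is.null(x$pi))
    cat(sprintf("non-null marker proportion (1 - pi): %.3f +/- %.3f\n",
                x$pi$nonnull$mean, x$pi$nonnull$sd))
  invisible(x)
}

#' Predict linear-predictor risk scores for new subjects
#'
#' `eta = W alpha_hat + X_c beta_hat`, centering the new dosages with the
#' allele frequencies of the training fit.  GRM-parameterized fits carry
#' no marker effects and cannot predict unseen subjects; refit with
#' `gblup-brr` (the equivalent ridge parameterization) for prediction.
#'
#' @param object a `wgr_fit`.
#' @param fixed_design covariate matrix with the training columns.
#' @param genotypes dosage matrix / `genotype_matrix` for the new subjects
#'   (required for marker-family fits).
#' @param ... unused.
#' @return numeric vector of risk scores `eta_hat`.
#' @export
predict.wgr_fit <- function(object, fixed_design, genotypes = NULL, ...) {
  W <- as.matrix(fixed_design)
  stopifnot(ncol(W) == length(object$alpha$mean))
  eta <- drop(W %*% object$alpha$mean)
  if (length(object$beta$mean)) {
    if (is.null(genotypes))
      stop("marker-family fit needs genotypes for prediction",
           call. = FALSE)
    X <- if (inherits(genotypes, "genotype_matrix"))
      unclass_dosages(genotypes) else as.matrix(genotypes)
    if (!is.null(object$center_freq))
      X <- sweep(X, 2L, 2 * object$center_freq)
    eta <- eta + drop(X %*% object$beta$mean)
  } else if (object$prior_family == "gblup-grm") {
    stop("gblup-grm fits cannot predict new subjects; use gblup-brr",
         call. = FALSE)
  }
  eta
}

#' Summarize MCMC traces
#'
#' Discards burn-in, thins, and returns per-parameter posterior means and
#' SDs plus a Geweke-style stationarity z-score (first 10% vs last 50% of
#' the retained chain, spectral variance estimates) as an automated
#' convergence screen.
#'
#' @param samples matrix of traces, one column per parameter, one row per
#'   iteration (all iterations, burn-in included).
#' @param mcmc the [mcmc_config()] describing the chain.
#' @return list with `mean`, `sd`, `geweke_z` (named vectors), `retained`
#'   (row indices kept) and `samples` (the retained submatrix).
#' @export
posterior_summary <- function(samples, mcmc) {
  samples <- as.matrix(samples)
  if (mcmc$burn_in >= nrow(samples))
    stop("burn_in leaves no retained samples", call. = FALSE)
  retained <- seq.int(mcmc$burn_in + 1L, nrow(samples), by = mcmc$thin)
  if (length(retained) < 100L)
    warning("fewer than 100 retained samples; summaries will be noisy",
            call. = FALSE)
  S <- samples[retained, , drop = FALSE]
  list(mean = apply(S, 2L, mean),
       sd = apply(S, 2L, stats::sd),
       geweke_z = apply(S, 2L, geweke_z),
       retained = retained,
       samples = S)
}

#' Geweke stationarity z-score
#'
#' Compares the mean of the first `frac1` and last `frac2` of a chain,
#' with spectral-density variance estimates (AR fit); |z| > 2 flags
#' non-stationarity.  Constant chains return 0.
#'
#' @param x numeric chain.
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return scalar z-score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 10L) return(NA_real_)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[seq.int(n - max(2, floor(frac2 * n)) + 1L, n)]
  s1 <- spectrum0(x1); s2 <- spectrum0(x2)
  if (s1 <= 0 && s2 <= 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

# spectral density at frequency zero via an AR fit (naive variance as
# fallback for very short or degenerate chains)
spectrum0 <- function(v) {
  if (length(v) < 2L || !is.finite(stats::var(v)) || stats::var(v) == 0)
    return(0)
  fit <- tryCatch(stats::ar(v, aic = TRUE,
                            order.max = min(20L, length(v) - 2L)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0L) return(stats::var(v))
  fit$var.pred / (1 - sum(fit$ar))^2
}
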
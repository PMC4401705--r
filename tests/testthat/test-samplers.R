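test_that("latent-liability draws respect truncation and moments", {
  set.seed(1)
  y <- rep(1L, 1e5)
  z <- update_latent_liability(rep(0, 1e5), y)
  expect_true(all(z > 0))
  # half-normal mean sqrt(2/pi), SD of the mean from half-normal variance
  hn_sd <- sqrt(1 - 2 / pi)
  expect_lt(abs(mean(z) - sqrt(2 / pi)), 3 * hn_sd / sqrt(1e5))

  # far from the threshold the truncation is negligible
  z10 <- update_latent_liability(rep(10, 1e5), rep(1L, 1e5))
  expect_lt(abs(mean(z10) - 10), 3 / sqrt(1e5))

  # numerically robust deep-tail sampling
  zneg <- update_latent_liability(rep(-12, 1000), rep(1L, 1000))
  expect_true(all(is.finite(zneg) & zneg > 0))
  zpos <- update_latent_liability(rep(12, 1000), rep(0L, 1000))
  expect_true(all(is.finite(zpos) & zpos <= 0))

  z0 <- update_latent_liability(rep(0.3, 50), rep(0L, 50))
  expect_true(all(z0 <= 0))
})

test_that("flat-prior fixed effects agree with maximum-likelihood probit", {
  set.seed(21)
  n <- 800
  W <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  eta <- drop(W %*% c(-0.3, 0.5, -0.4))
  y <- as.integer(runif(n) < pnorm(eta))
  fit <- fit_probit_wgr(y, W, NULL, model_spec("fixed-only"),
                        mcmc_config(4000, 1000, 2, seed = 5))
  ml <- glm(y ~ W - 1, family = binomial(link = "probit"))
  se <- summary(ml)$coefficients[, 2]
  expect_true(all(abs(fit$alpha$mean - coef(ml)) < se))
})

test_that("rank-deficient fixed designs fail naming the column", {
  W <- cbind(intercept = 1, x = 1:10, copy = 1:10)
  y <- rep(0:1, 5)
  expect_error(fit_probit_wgr(y, W, NULL, model_spec("fixed-only")),
               "copy|collinear")
  expect_error(sample_fixed_effects(W, rnorm(10)), "collinear")
})

test_that("quasi-separation triggers the divergence guard", {
  set.seed(3)
  W <- cbind(1, c(rep(0, 25), rep(1, 25)))
  y <- c(rep(0L, 25), rep(1L, 25))        # perfectly separated covariate
  expect_warning(
    fit_probit_wgr(y, W, NULL, model_spec("fixed-only", alpha_bound = 4),
                   mcmc_config(800, 200, 1, seed = 2)),
    "quasi-separation")
})

test_that("marker-effect conditional matches hand conjugate algebra", {
  set.seed(7)
  # x = (1, -1), partial residual (1, -1), sigma2 = 1: C = 3, mean 2/3
  d <- sample_marker_effect(c(1, -1), c(1, -1), 1, n_draws = 1e5)
  expect_lt(abs(mean(d) - 2 / 3), 3 * sqrt(1 / 3) / sqrt(1e5))
  expect_lt(abs(var(d) - 1 / 3), 3 * (1 / 3) * sqrt(2 / 1e5))
  # infinite-shrinkage limit
  expect_true(all(abs(sample_marker_effect(c(1, -1), c(1, -1), 1e-12,
                                           n_draws = 100)) < 1e-4))
  expect_identical(sample_marker_effect(c(1, -1), c(1, -1), 0,
                                        n_draws = 3), rep(0, 3))
})

test_that("per-marker variance update matches the inverse-chi-square", {
  set.seed(9)
  df <- 5; S <- 0.4
  # beta = 0: scaled-inv-chisq(df+1, df*S/(df+1)); mean df*S/(df-1)
  d <- update_variance_bayes_a(rep(0, 1e5), df, S)
  expect_true(all(d > 0))
  m_true <- df * S / (df - 1)
  # var of scinvchisq(nu, s): 2 nu^2 s^2 / ((nu-2)^2 (nu-4))
  nu <- df + 1; s <- df * S / nu
  v_true <- 2 * nu^2 * s^2 / ((nu - 2)^2 * (nu - 4))
  expect_lt(abs(mean(d) - m_true), 3 * sqrt(v_true / 1e5))
  # stochastically larger for larger |beta|
  d2 <- update_variance_bayes_a(rep(2, 1e4), df, S)
  expect_gt(mean(d2), mean(update_variance_bayes_a(rep(0, 1e4), df, S)))
})

test_that("spike-and-slab pi update has the Beta posterior mean", {
  set.seed(11)
  p <- 500
  draws <- replicate(2e4, sample_pi(0, p, c(1, 1)))
  m_true <- 1 / (p + 2)
  v_true <- m_true * (1 - m_true) / (p + 3)
  expect_lt(abs(mean(draws) - m_true), 3 * sqrt(v_true / 2e4))
})

test_that("degenerate null mass reduces the mixture to ridge", {
  co <- small_cohort(n_families = 25, p = 60, seed = 14)
  W <- cohort_design(co)
  y <- co$phenotypes$y
  mc <- mcmc_config(600, 200, 1, seed = 8)
  bc <- fit_probit_wgr(y, W, co$genotypes,
                       model_spec("bayes-c-pi",
                                  pi_prior = c(prob = 0, counts = 1e6),
                                  fixed_variances = TRUE,
                                  sigma2_beta_fixed = 0.01), mc)
  rr <- fit_probit_wgr(y, W, co$genotypes,
                       model_spec("gblup-brr", fixed_variances = TRUE,
                                  sigma2_beta_fixed = 0.01), mc)
  # all markers always included: identical Gibbs path under the same seed
  expect_equal(bc$beta$mean, rr$beta$mean, tolerance = 1e-10)
  expect_true(all(bc$pi$samples == 0))
})

test_that("LASSO scale updates match inverse-Gaussian moments", {
  set.seed(13)
  spec <- model_spec("b-lasso")
  expect_equal(spec$lasso_shape, 0.55)
  expect_equal(spec$lasso_rate, 1e-4)
  ls <- update_lasso_scales(rnorm(500), lambda2 = 2)
  expect_true(all(ls$tau2 > 0))
  expect_gt(ls$lambda2, 0)
  # 1e5 inverse-Gaussian draws: sample mean within 3 SE of mu
  mu <- 0.8; lam <- 2.5
  d <- rinvgauss(1e5, mu, lam)
  sd_ig <- sqrt(mu^3 / lam)
  expect_lt(abs(mean(d) - mu), 3 * sd_ig / sqrt(1e5))
  # zero-effect guard draws from the exponential prior
  ls0 <- update_lasso_scales(numeric(10), lambda2 = 3)
  expect_true(all(ls0$tau2 > 0))
})

test_that("identity-GRM genomic update decouples into conjugate draws", {
  set.seed(15)
  n <- 12
  eig <- eigen(diag(n), symmetric = TRUE)
  r <- rnorm(n, 0, 2)
  s2 <- 1.5
  draws <- replicate(2e4, update_sigma_u(r, eig, s2, df = 5, S = 1)$u)
  # conditional per coordinate: N(r * s2/(1+s2), s2/(1+s2))
  pv <- s2 / (1 + s2)
  expect_lt(max(abs(rowMeans(draws) - pv * r)), 4 * sqrt(pv / 2e4) * 3)
  expect_lt(max(abs(apply(draws, 1, var) - pv)),
            3 * pv * sqrt(2 / 2e4) * 3)
  expect_error(update_sigma_u(r, eigen(diag(-1, n)), s2, 5, 1), "semidef")
})

test_that("identity-link chain with fixed variances matches closed-form ridge", {
  set.seed(17)
  n <- 80; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  Xc <- scale(X, scale = FALSE)
  beta_t <- rnorm(p, 0, 0.5)
  y <- 0.4 + drop(Xc %*% beta_t) + rnorm(n)
  W <- matrix(1, n, 1)
  s2 <- 0.3
  fit <- fit_probit_wgr(y, W, Xc,
                        model_spec("gblup-brr", link = "identity",
                                   fixed_variances = TRUE,
                                   sigma2_beta_fixed = s2),
                        mcmc_config(6000, 1000, 1, seed = 3))
  # joint flat-intercept + ridge posterior mean
  C <- cbind(W, Xc)
  P <- diag(c(0, rep(1 / s2, p)))
  mpost <- solve(crossprod(C) + P, crossprod(C, y))
  # MC error bound: 2 x (posterior SD / sqrt(effective draws))
  tol <- pmax(2 * c(fit$alpha$sd, fit$beta$sd) / sqrt(5000 / 10), 0.005)
  expect_true(all(abs(c(fit$alpha$mean, fit$beta$mean) - mpost) < tol))
})

test_that("chains are bit-reproducible and centering-invariant", {
  co <- small_cohort(n_families = 20, p = 50, seed = 19)
  W <- cohort_design(co)
  y <- co$phenotypes$y
  mc <- mcmc_config(400, 100, 1, seed = 31)
  f1 <- fit_probit_wgr(y, W, co$genotypes, model_spec("gblup-brr"), mc)
  f2 <- fit_probit_wgr(y, W, co$genotypes, model_spec("gblup-brr"), mc)
  expect_identical(f1$summary$samples, f2$summary$samples)
  expect_identical(f1$eta_hat, f2$eta_hat)

  # adding a constant to one marker's dosages leaves risk scores unchanged
  # (the sampler centers at 2q, which absorbs the shift)
  X <- unclass_dosages(co$genotypes)
  X2 <- X; X2[, 5] <- X2[, 5] - 1
  f3 <- fit_probit_wgr(y, W, X2, model_spec("gblup-brr"), mc)
  expect_equal(f3$eta_hat, f1$eta_hat, tolerance = 1e-10)
})

test_that("posterior summaries honor burn-in, thinning and degeneracies", {
  x <- cbind(par = c(rep(0, 50), rnorm(500, 3, 2)))
  mc <- mcmc_config(550, 50, 1, seed = 1)
  s <- posterior_summary(x, mc)
  expect_equal(s$mean[["par"]], mean(x[51:550, 1]))
  expect_equal(s$sd[["par"]], sd(x[51:550, 1]))
  # constant chain: zero SD, zero Geweke score
  sc <- suppressWarnings(
    posterior_summary(cbind(rep(2, 200)), mcmc_config(200, 100, 1)))
  expect_equal(sc$sd[[1]], 0)
  expect_equal(sc$geweke_z[[1]], 0)
  expect_warning(posterior_summary(cbind(rnorm(200)),
                                   mcmc_config(200, 199, 1)), "fewer than")
  expect_error(posterior_summary(cbind(rnorm(100)),
                                 mcmc_config(200, 150, 1)), "retained")
})

test_that("prior and Gibbs kernel are mutually consistent (Geweke check)", {
  # successive-conditional simulator: alternating data simulation and one
  # Gibbs cycle leaves the prior invariant, so the sigma2_beta chain must
  # average to its prior mean df*S/(df-2).
  set.seed(23)
  n <- 20; p <- 3; df <- 6; S <- 0.5
  X <- matrix(rnorm(n * p), n, p)
  xtx <- colSums(X^2)
  iters <- 4000
  s2 <- df * S / (df - 2)
  beta <- rnorm(p, 0, sqrt(s2))
  out <- numeric(iters)
  for (t in seq_len(iters)) {
    y <- drop(X %*% beta) + rnorm(n)             # data | parameters
    resid <- y - drop(X %*% beta)
    for (j in seq_len(p)) {                      # parameters | data
      r_j <- resid + X[, j] * beta[j]
      bnew <- sample_marker_effect(X[, j], r_j, s2)
      resid <- r_j - X[, j] * bnew
      beta[j] <- bnew
    }
    s2 <- rscinvchisq(1, df + p, (df * S + sum(beta^2)) / (df + p))
    out[t] <- s2
  }
  prior_mean <- df * S / (df - 2)
  # batch-means SE to absorb autocorrelation
  bm <- tapply(out, rep(1:40, each = iters / 40), mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(out) - prior_mean), 4 * se + 0.02)
})
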
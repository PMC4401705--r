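#include <Rcpp.h>
using namespace Rcpp;

// Per-marker Gibbs sweeps.  These mutate `resid` and `beta` in place:
// callers own both vectors and must not share them.  All randomness goes
// through R's RNG so chains are reproducible under set.seed().

// beta_j ~ N(c/C, 1/C), C = x'x + 1/prior_var_j, c = x'(partial residual).
// Shared by Bayesian ridge (scalar prior_var recycled by caller into a
// vector), Bayes A (per-marker variances) and the Bayesian LASSO (tau2_j).
// [[Rcpp::export]]
void sweep_normal(const NumericMatrix& X, NumericVector resid,
                  NumericVector beta, const NumericVector& prior_var,
                  const NumericVector& xtx) {
  const int n = X.nrow(), p = X.ncol();
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double bold = beta[j];
    if (prior_var[j] < 1e-300) {
      if (bold != 0.0)
        for (int i = 0; i < n; ++i) resid[i] += xj[i] * bold;
      beta[j] = 0.0;
      continue;
    }
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += xj[i] * resid[i];
    double C = xtx[j] + 1.0 / prior_var[j];
    double c = dot + xtx[j] * bold;
    double bnew = c / C + norm_rand() / std::sqrt(C);
    double diff = bnew - bold;
    for (int i = 0; i < n; ++i) resid[i] -= xj[i] * diff;
    beta[j] = bnew;
  }
}

// Spike-and-slab sweep: inclusion sampled from the marginal odds with
// beta_j integrated out, then beta_j drawn (0 when excluded).  pi_null is
// the prior mass at zero; pi_null <= 0 forces inclusion (ridge limit).
// Returns the number of included markers.
// [[Rcpp::export]]
int sweep_mixture(const NumericMatrix& X, NumericVector resid,
                  NumericVector beta, IntegerVector delta,
                  double sigma2_beta, double pi_null,
                  const NumericVector& xtx) {
  const int n = X.nrow(), p = X.ncol();
  int n_in = 0;
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double bold = beta[j];
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += xj[i] * resid[i];
    double C = xtx[j] + 1.0 / sigma2_beta;
    double c = dot + xtx[j] * bold;
    // degenerate masses skip the inclusion draw entirely, so pi_null = 0
    // reproduces the ridge sweep's RNG path exactly
    bool include;
    if (pi_null <= 0.0) include = true;
    else if (pi_null >= 1.0) include = false;
    else {
      double log_odds = std::log((1.0 - pi_null) / pi_null)
        - 0.5 * std::log(sigma2_beta * C) + 0.5 * c * c / C;
      include = unif_rand() < 1.0 / (1.0 + std::exp(-log_odds));
    }
    double bnew;
    if (include) {
      delta[j] = 1; ++n_in;
      bnew = c / C + norm_rand() / std::sqrt(C);
    } else {
      delta[j] = 0;
      bnew = 0.0;
    }
    double diff = bnew - bold;
    if (diff != 0.0)
      for (int i = 0; i < n; ++i) resid[i] -= xj[i] * diff;
    beta[j] = bnew;
  }
  return n_in;
}
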
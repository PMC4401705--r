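# Small cohort fixtures built in code; sizes chosen so the whole suite
# stays desk-scale.

small_cohort <- function(n_families = 60, fam_range = c(4, 6), p = 300,
                         h2 = 0.5, pi_nonnull = 1, seed = 42) {
  simulate_cohort(sim_config(n_families = n_families,
                             family_size_range = fam_range,
                             p_markers = p, h2_target = h2,
                             pi_nonnull = pi_nonnull, seed = seed))
}

cohort_design <- function(co) {
  cbind(intercept = 1, sex = co$covariates$sex,
        cohort = co$covariates$cohort, age = co$covariates$age)
}

# O(n^2) brute-force AUC: the independent oracle for the rank-based
# implementation (ties scored one half).
auc_bruteforce <- function(y, s) {
  cases <- s[y == 1]; ctrls <- s[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}
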
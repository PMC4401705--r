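#' Simulation configuration for a synthetic family cohort
#'
#' Bundles every knob of the cohort generator: family structure, marker
#' panel, genetic architecture and non-genetic covariate effects on the
#' liability scale.  Defaults emulate a two-generation longitudinal family
#' study of type 2 diabetes: ~18% case prevalence (939/5245), sex and
#' cohort dummies with liability effects -0.26 and -0.40, an
#' age-at-last-contact effect of 0.016 per year over ages 34-104.
#'
#' @param n_families number of independent families.
#' @param family_size_range integer pair, inclusive range of family sizes
#'   (a family of size >= 3 is two founder parents plus offspring).
#' @param p_markers number of SNP markers.
#' @param maf_range pair in (0, 0.5]; founder allele frequencies are drawn
#'   uniformly on this interval.
#' @param h2_target liability-scale genomic heritability in `[0, 1)`; the
#'   additive genetic variance is `h2/(1 - h2)` since the residual liability
#'   variance is 1.
#' @param pi_nonnull fraction of markers with non-zero effects, in (0, 1].
#' @param prevalence_target population case fraction in (0, 1).
#' @param covariate_effects named numeric vector with elements `sex`,
#'   `cohort`, `age` (liability-scale effects; age is per year).
#' @param age_range pair, uniform window for age at last contact.
#' @param seed integer seed making the whole cohort reproducible.
#'
#' @return An object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(n_families = 150,
                       family_size_range = c(3L, 7L),
                       p_markers = 2000L,
                       maf_range = c(0.05, 0.5),
                       h2_target = 0.5,
                       pi_nonnull = 1,
                       prevalence_target = 939 / 5245,
                       covariate_effects = c(sex = -0.26, cohort = -0.40,
                                             age = 0.016),
                       age_range = c(34, 104),
                       seed = 1L) {
  stopifnot(length(family_size_range) == 2L, length(maf_range) == 2L,
            length(age_range) == 2L)
  if (n_families < 1L || p_markers < 1L)
    stop("n_families and p_markers must be >= 1", call. = FALSE)
  if (family_size_range[1] > family_size_range[2] ||
      maf_range[1] > maf_range[2] || age_range[1] > age_range[2])
    stop("ranges must be well-ordered", call. = FALSE)
  if (family_size_range[1] < 1L)
    stop("family sizes must be >= 1", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie in (0, 0.5]", call. = FALSE)
  if (h2_target < 0 || h2_target >= 1)
    stop("h2_target must lie in [0, 1)", call. = FALSE)
  if (pi_nonnull <= 0 || pi_nonnull > 1)
    stop("pi_nonnull must lie in (0, 1]", call. = FALSE)
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must lie in (0, 1)", call. = FALSE)
  stopifnot(all(c("sex", "cohort", "age") %in% names(covariate_effects)))
  structure(list(n_families = as.integer(n_families),
                 family_size_range = as.integer(family_size_range),
                 p_markers = as.integer(p_markers),
                 maf_range = maf_range,
                 h2_target = h2_target,
                 pi_nonnull = pi_nonnull,
                 prevalence_target = prevalence_target,
                 covariate_effects = covariate_effects,
                 age_range = age_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-generation pedigree
#'
#' Families of size 1 are a single founder; size 2 gives two unrelated
#' founders; size >= 3 gives a founder couple (generation 0) plus
#' full-sibling offspring (generation 1), mirroring an "Original cohort"
#' plus "Offspring cohort" sampling design.
#'
#' @param n_families number of families (>= 1).
#' @param family_size_range inclusive integer range of family sizes.
#' @param seed integer seed.
#' @return data.frame with columns `individual_id`, `father_id`,
#'   `mother_id` (NA for founders), `family_id`, `generation`.
#' @export
simulate_pedigree <- function(n_families, family_size_range = c(3L, 7L),
                              seed = 1L) {
  if (n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  family_size_range <- as.integer(rep(family_size_range, length.out = 2L))
  if (any(family_size_range < 1L) ||
      family_size_range[1] > family_size_range[2])
    stop("family_size_range must be a well-ordered pair of sizes >= 1",
         call. = FALSE)
  set.seed(seed)
  sizes <- sample.int(family_size_range[2] - family_size_range[1] + 1L,
                      n_families, replace = TRUE) + family_size_range[1] - 1L
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%04d", f)
    sz <- sizes[f]
    if (sz <= 2L) {
      rows[[f]] <- data.frame(
        individual_id = sprintf("%s_I%02d", fam, seq_len(sz)),
        father_id = NA_character_, mother_id = NA_character_,
        family_id = fam, generation = 0L, stringsAsFactors = FALSE)
    } else {
      founders <- sprintf("%s_I%02d", fam, 1:2)
      kids <- sprintf("%s_I%02d", fam, 3:sz)
      rows[[f]] <- data.frame(
        individual_id = c(founders, kids),
        father_id = c(NA_character_, NA_character_,
                      rep(founders[1], sz - 2L)),
        mother_id = c(NA_character_, NA_character_,
                      rep(founders[2], sz - 2L)),
        family_id = fam,
        generation = c(0L, 0L, rep(1L, sz - 2L)),
        stringsAsFactors = FALSE)
    }
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' Checks unique ids, that every named parent exists within the same family,
#' and that generations are consistent (a parent's generation precedes its
#' child's, so nobody is their own ancestor).
#'
#' @param ped pedigree data.frame as from [simulate_pedigree()].
#' @return the pedigree, invisibly; errors otherwise.
#' @export
validate_pedigree <- function(ped) {
  need <- c("individual_id", "father_id", "mother_id", "family_id",
            "generation")
  if (!is.data.frame(ped) || !all(need %in% names(ped)))
    stop("pedigree must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(ped) == 0L) stop("pedigree is empty", call. = FALSE)
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual_id in pedigree", call. = FALSE)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$individual_id)
  for (col in c("father_id", "mother_id")) {
    p <- ped[[col]]
    has <- !is.na(p)
    if (any(has)) {
      if (!all(p[has] %in% names(idx)))
        stop("parent ids missing from pedigree: ",
             paste(setdiff(p[has], names(idx)), collapse = ", "),
             call. = FALSE)
      if (!all(ped$family_id[idx[p[has]]] == ped$family_id[has]))
        stop("parent and child in different families", call. = FALSE)
      if (!all(ped$generation[idx[p[has]]] < ped$generation[has]))
        stop("parent generation must precede child generation",
             call. = FALSE)
    }
  }
  invisible(ped)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders receive two independent alleles per marker with frequencies
#' drawn uniformly from `maf_range`; each offspring inherits one allele per
#' parent per marker (transmission probability `dosage/2`, exact for
#' unlinked markers).  Markers are in linkage equilibrium among founders;
#' within-family correlation arises purely from co-inheritance.
#'
#' @param pedigree data.frame from [simulate_pedigree()].
#' @param p_markers number of markers (>= 1).
#' @param maf_range founder allele-frequency window in (0, 0.5].
#' @param seed integer seed.
#' @return a `genotype_matrix` (see [genotype_matrix()]) with integer
#'   dosages in `{0, 1, 2}`, plus attribute `founder_freq` (the q_j used).
#' @export
simulate_genotypes <- function(pedigree, p_markers, maf_range = c(0.05, 0.5),
                               seed = 1L) {
  validate_pedigree(pedigree)
  if (p_markers < 1L) stop("p_markers must be >= 1", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be a well-ordered pair in (0, 0.5]", call. = FALSE)
  set.seed(seed)
  n <- nrow(pedigree)
  p <- as.integer(p_markers)
  q <- stats::runif(p, maf_range[1], maf_range[2])
  X <- matrix(NA_integer_, n, p)
  ord <- order(pedigree$generation)         # parents simulated before kids
  idx <- stats::setNames(seq_len(n), pedigree$individual_id)
  founder <- is.na(pedigree$father_id)
  nf <- sum(founder)
  X[founder, ] <- matrix(stats::rbinom(nf * p, 2L, rep(q, each = nf)), nf, p)
  for (i in ord[!founder[ord]]) {
    dp <- X[idx[pedigree$father_id[i]], ]
    dm <- X[idx[pedigree$mother_id[i]], ]
    X[i, ] <- stats::rbinom(p, 1L, dp / 2) + stats::rbinom(p, 1L, dm / 2)
  }
  G <- genotype_matrix(X, subject_ids = pedigree$individual_id,
                       marker_ids = sprintf("snp%05d", seq_len(p)))
  attr(G, "founder_freq") <- q
  G
}

#' Simulate non-genetic covariates
#'
#' Sex is Bernoulli(0.55) female; the cohort dummy is the pedigree
#' generation (0 = original cohort, 1 = offspring); age at last contact is
#' uniform over `age_range` (default 34-104 years).
#'
#' @param pedigree data.frame from [simulate_pedigree()].
#' @param age_range uniform age window.
#' @param p_female probability an individual is female.
#' @param seed integer seed.
#' @return data.frame with `individual_id`, `sex` (1 = female), `cohort`,
#'   `age`.
#' @export
simulate_covariates <- function(pedigree, age_range = c(34, 104),
                                p_female = 0.55, seed = 1L) {
  validate_pedigree(pedigree)
  set.seed(seed)
  n <- nrow(pedigree)
  data.frame(individual_id = pedigree$individual_id,
             sex = stats::rbinom(n, 1L, p_female),
             cohort = as.integer(pedigree$generation),
             age = stats::runif(n, age_range[1], age_range[2]),
             stringsAsFactors = FALSE)
}

# Intercept t such that mean(pnorm(t + m)) = target, by bisection on the
# monotone map t -> mean prevalence.  Deterministic; tolerance 1e-6.
solve_prevalence_intercept <- function(m, target, tol = 1e-6) {
  f <- function(t) mean(stats::pnorm(t + m)) - target
  lo <- -20; hi <- 20
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a liability-threshold binary phenotype
#'
#' Draws a sparse (or dense) additive architecture, scales the non-null
#' effect variance so the genetic-value variance matches
#' `sigma_u^2 = h2/(1 - h2)` against the realized genotypes' empirical
#' `sum 2 q_j (1 - q_j)`, adds covariate effects and standard-normal
#' residual liability, and thresholds at zero.  The intercept is solved by
#' bisection so the expected case fraction matches `prevalence_target`.
#'
#' @param genotypes a `genotype_matrix` without missing values.
#' @param covariates data.frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data.frame: `individual_id`, `y`,
#'   `liability`, `genetic_value`) and `truth` (list: `beta_true`,
#'   `nonnull_mask`, `sigma_u2_true`, `alpha_true`, `intercept`,
#'   `realized_h2`).
#' @export
simulate_phenotypes <- function(genotypes, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$h2_target >= 1)
    stop("h2_target must be < 1", call. = FALSE)
  X <- unclass_dosages(genotypes)
  if (anyNA(X)) stop("genotypes must be complete (impute first)",
                     call. = FALSE)
  stopifnot(nrow(X) == nrow(covariates))
  set.seed(config$seed + 104729L)  # offset so genotype draws are untouched
  n <- nrow(X); p <- ncol(X)
  q <- colMeans(X) / 2
  Xc <- sweep(X, 2L, 2 * q)
  sigma_u2 <- config$h2_target / (1 - config$h2_target)

  nonnull <- stats::runif(p) < config$pi_nonnull
  beta <- numeric(p)
  if (config$h2_target > 0 && any(nonnull)) {
    # per-marker slab variance from the realized 2q(1-q) of non-null markers
    denom <- sum(2 * q[nonnull] * (1 - q[nonnull]))
    if (denom <= 0) stop("all non-null markers monomorphic", call. = FALSE)
    beta[nonnull] <- stats::rnorm(sum(nonnull), 0, sqrt(sigma_u2 / denom))
  } else {
    nonnull[] <- nonnull & (config$h2_target > 0)
  }
  g <- drop(Xc %*% beta)

  eff <- config$covariate_effects
  cov_term <- eff[["sex"]] * covariates$sex +
    eff[["cohort"]] * covariates$cohort + eff[["age"]] * covariates$age
  m <- cov_term + g
  a0 <- solve_prevalence_intercept(m, config$prevalence_target)
  z <- a0 + m + stats::rnorm(n)
  y <- as.integer(z > 0)

  vg <- stats::var(g)
  list(
    phenotypes = data.frame(individual_id = covariates$individual_id,
                            y = y, liability = z, genetic_value = g,
                            stringsAsFactors = FALSE),
    truth = list(beta_true = beta, nonnull_mask = nonnull,
                 sigma_u2_true = sigma_u2,
                 alpha_true = c(intercept = a0, eff),
                 intercept = a0,
                 realized_h2 = vg / (vg + 1))
  )
}

#' Simulate a complete synthetic family cohort
#'
#' Convenience wrapper running pedigree, genotype, covariate and phenotype
#' simulation from a single [sim_config()] (sub-seeds are derived from
#' `config$seed` so each stage is independently reproducible).
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `genotypes`, `covariates`, `phenotypes`,
#'   `truth` and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ped <- simulate_pedigree(config$n_families, config$family_size_range,
                           seed = config$seed)
  gen <- simulate_genotypes(ped, config$p_markers, config$maf_range,
                            seed = config$seed + 1L)
  cov <- simulate_covariates(ped, config$age_range, seed = config$seed + 2L)
  phe <- simulate_phenotypes(gen, cov, config)
  list(pedigree = ped, genotypes = gen, covariates = cov,
       phenotypes = phe$phenotypes, truth = phe$truth, config = config)
}

#' Write a simulated cohort to plain-text files
#'
#' Pedigree, covariate, phenotype and ground-truth tables as TSV;
#' genotypes as TSV dosage (and optionally PLINK .bed/.bim/.fam).
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param plink also write a PLINK fileset.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, plink = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  wtsv <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  out <- c(out, wtsv(cohort$pedigree, "pedigree.tsv"),
           wtsv(cohort$covariates, "covariates.tsv"),
           wtsv(cohort$phenotypes, "phenotypes.tsv"))
  tr <- cohort$truth
  out <- c(out, wtsv(data.frame(marker_id = marker_ids(cohort$genotypes),
                                beta_true = tr$beta_true,
                                nonnull = as.integer(tr$nonnull_mask)),
                     "true_architecture.tsv"))
  f <- file.path(dir, "genotypes.tsv")
  write_dosage_tsv(cohort$genotypes, f)
  out <- c(out, f)
  if (plink) {
    write_plink(cohort$genotypes, file.path(dir, "genotypes"),
                pedigree = cohort$pedigree)
    out <- c(out, file.path(dir, paste0("genotypes.",
                                        c("bed", "bim", "fam"))))
  }
  invisible(out)
}
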
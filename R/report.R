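#' Convert a liability-scale coefficient to an odds ratio
#'
#' `exp(coefficient)`.  For probit (liability-scale) effects this is an
#' approximation — the exact odds ratio depends on the covariate
#' configuration — but it is the conversion conventionally printed next to
#' such coefficients (e.g. -0.26 -> 0.77, 0.016 -> 1.02 at two decimals).
#'
#' @param coefficient finite numeric coefficient(s).
#' @return odds ratio(s).
#' @export
effect_to_odds_ratio <- function(coefficient) {
  stopifnot(all(is.finite(coefficient)))
  exp(coefficient)
}

#' Per-subject genetic risk scores from marker effects
#'
#' `score_i = sum_j (x_ij - 2 q_j) beta_hat_j` on centered dosages, with
#' the min / max / mean +/- SD summary block conventionally reported for
#' genetic scores.
#'
#' @param marker_effects named numeric vector of effect estimates.
#' @param genotypes dosage matrix / `genotype_matrix`; columns must cover
#'   every effect's marker id.
#' @param center_freq optional allele frequencies used for centering
#'   (default: re-estimated from `genotypes`).
#' @return list of class `genetic_scores`: data.frame `scores`
#'   (`subject_id`, `score`) and `summary` (min, max, mean, sd).
#' @export
genetic_score_table <- function(marker_effects, genotypes,
                                center_freq = NULL) {
  X <- if (inherits(genotypes, "genotype_matrix"))
    unclass_dosages(genotypes) else as.matrix(genotypes)
  ids <- names(marker_effects)
  if (is.null(ids)) {
    if (length(marker_effects) != ncol(X))
      stop("unnamed effects must match the genotype column count",
           call. = FALSE)
  } else {
    missing <- setdiff(ids, colnames(X))
    if (length(missing))
      stop("markers absent from genotypes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- X[, ids, drop = FALSE]
  }
  q <- if (is.null(center_freq)) colMeans(X) / 2 else center_freq
  s <- drop(sweep(X, 2L, 2 * q) %*% as.numeric(marker_effects))
  structure(list(
    scores = data.frame(subject_id = rownames(X) %||%
                          sprintf("S%04d", seq_len(nrow(X))),
                        score = s, stringsAsFactors = FALSE),
    summary = c(min = min(s), max = max(s), mean = mean(s),
                sd = stats::sd(s))), class = "genetic_scores")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genetic_scores <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "genetic score: ranged from %.3f to %.3f, centered at %.3f+/-%.3f\n",
    s["min"], s["max"], s["mean"], s["sd"]))
  invisible(x)
}

#' Marker effects ordered by estimate, with a highlight flag
#'
#' Sorts markers by posterior-mean effect and flags a supplied id list
#' (e.g. externally established risk SNPs) so their position in the
#' effect distribution can be inspected or plotted.
#'
#' @param marker_effects named numeric vector of posterior-mean effects.
#' @param highlight_ids marker ids to flag (unknown ids raise a warning).
#' @return data.frame `marker_id`, `effect`, `rank`, `highlight`, ordered
#'   by effect.
#' @export
effect_rank_export <- function(marker_effects, highlight_ids = character(0)) {
  ids <- names(marker_effects)
  if (is.null(ids)) ids <- sprintf("snp%05d", seq_along(marker_effects))
  unknown <- setdiff(highlight_ids, ids)
  if (length(unknown))
    warning("highlight ids not present: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  o <- order(marker_effects)
  data.frame(marker_id = ids[o], effect = as.numeric(marker_effects)[o],
             rank = seq_along(o), highlight = ids[o] %in% highlight_ids,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> QC -> (optional down-sampling) -> imputation -> GRM ->
#' ancestry PCs -> probit fits for each requested prior family ->
#' family-blocked cross-validation -> comparison report: the standard
#' model sequence for assessing whole-genome regression of a binary
#' trait, from a covariates-only baseline up to genome-wide models.
#'
#' @param config list with components `sim` (a [sim_config()]), `families`
#'   (character vector of prior families to fit; `"fixed-only"` is always
#'   included as the baseline), `mcmc` (an [mcmc_config()]), `cv_k` (folds,
#'   default 10), `downsample` (marker fraction, default 1), `out_dir`
#'   (optional; artifacts written there as TSV/JSON when given).
#' @return list of class `wgr_pipeline`: the cohort, QC report, GRM
#'   diagnostics, fits, CV results, and a Table-style AUC comparison
#'   (`auc_table`) plus the heritability summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), inherits(config$sim, "sim_config"))
  families <- unique(config$families %||% "gblup-brr")
  known <- c("bayes-a", "bayes-c-pi", "b-lasso", "gblup-brr", "gblup-grm")
  bad <- setdiff(families, known)
  if (length(bad))
    stop("unknown prior family: ", paste(bad, collapse = ", "),
         call. = FALSE)
  mcmc <- config$mcmc %||% mcmc_config(5000L, 2000L, 5L,
                                       seed = config$sim$seed)
  cv_k <- config$cv_k %||% 10L

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cohort <- stage("simulate", simulate_cohort(config$sim))
  qc <- stage("qc", qc_filter(cohort$genotypes))
  G <- qc$genotypes
  frac <- config$downsample %||% 1
  if (frac < 1)
    G <- stage("downsample",
               downsample_markers(G, frac, seed = config$sim$seed))
  G <- impute_missing(G)
  grm <- stage("grm", compute_grm(G))
  pcs <- stage("pcs", compute_pcs(G, k = 2L))

  W <- cbind(intercept = 1, sex = cohort$covariates$sex,
             cohort = cohort$covariates$cohort, age = cohort$covariates$age,
             pcs$scores)
  y <- cohort$phenotypes$y
  folds <- stage("folds",
                 assign_family_folds(cohort$pedigree, k = cv_k,
                                     seed = config$sim$seed))

  fits <- list()
  for (famly in families) {
    gen <- if (famly == "gblup-grm") grm else G
    fits[[famly]] <- stage(paste0("fit-", famly),
                           fit_probit_wgr(y, W, gen,
                                          spec = model_spec(famly),
                                          mcmc = mcmc))
  }

  cvs <- list()
  cvs[["fixed-only"]] <- stage("cv-baseline",
    cross_validate(y, W, NULL, folds, model_spec("fixed-only"), mcmc))
  for (famly in families)
    cvs[[famly]] <- stage(paste0("cv-", famly),
      cross_validate(y, W, G, folds, model_spec(famly), mcmc))

  auc_table <- data.frame(
    model = names(cvs),
    auc_mean = vapply(cvs, function(x) x$auc_mean, numeric(1)),
    auc_sd = vapply(cvs, function(x) x$auc_sd, numeric(1)),
    auc_pooled = vapply(cvs, function(x) x$auc_pooled, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  h2_table <- do.call(rbind, lapply(names(fits), function(fml) {
    h <- fits[[fml]]$h2
    data.frame(model = fml, sigma_u2 = h$sigma_u2$mean,
               sigma_u2_sd = h$sigma_u2$sd, h2 = h$h2$mean,
               h2_sd = h$h2$sd, stringsAsFactors = FALSE)
  }))

  out <- structure(list(cohort = cohort, qc_report = qc$report,
                        grm = grm, folds = folds, fits = fits, cv = cvs,
                        auc_table = auc_table, h2_table = h2_table,
                        mcmc = mcmc), class = "wgr_pipeline")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(auc_table,
                       file.path(config$out_dir, "auc_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(h2_table,
                       file.path(config$out_dir, "h2_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(qc = unclass(qc$report), auc = auc_table, h2 = h2_table),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' @export
print.wgr_pipeline <- function(x, ...) {
  cat("whole-genome regression pipeline\n")
  cat("cross-validated AUC (mean +/- SD across folds):\n")
  print(transform(x$auc_table,
                  auc = sprintf("%.3f +/- %.3f", auc_mean, auc_sd))[,
                  c("model", "auc")], row.names = FALSE)
  cat("\nheritability (liability scale):\n")
  print(transform(x$h2_table,
                  h2 = sprintf("%.3f +/- %.3f", h2, h2_sd))[,
                  c("model", "h2")], row.names = FALSE)
  invisible(x)
}
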
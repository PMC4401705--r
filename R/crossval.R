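#' Assign whole families to cross-validation folds
#'
#' Families are shuffled with the seed, then assigned greedily to the
#' currently smallest fold by subject count, so that no family is ever
#' split across folds and fold sizes stay balanced (max and min fold size
#' differ by at most the largest family).
#'
#' @param pedigree data.frame with `individual_id` and `family_id`.
#' @param k number of folds (default 10; must not exceed the number of
#'   families).
#' @param seed integer seed.
#' @return object of class `fold_assignment`: data.frame `subjects`
#'   (`individual_id`, `family_id`, `fold`) and the `family_to_fold` map.
#' @export
assign_family_folds <- function(pedigree, k = 10L, seed = 1L) {
  stopifnot(all(c("individual_id", "family_id") %in% names(pedigree)))
  fams <- unique(pedigree$family_id)
  if (k > length(fams))
    stop("k (", k, ") exceeds the number of families (", length(fams), ")",
         call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  set.seed(seed)
  fams <- sample(fams)
  sizes <- table(pedigree$family_id)[fams]
  fold_of <- integer(length(fams)); names(fold_of) <- fams
  load <- integer(k)
  for (f in seq_along(fams)) {
    target <- which.min(load)
    fold_of[f] <- target
    load[target] <- load[target] + sizes[f]
  }
  subjects <- data.frame(individual_id = pedigree$individual_id,
                         family_id = pedigree$family_id,
                         fold = unname(fold_of[pedigree$family_id]),
                         stringsAsFactors = FALSE)
  structure(list(k = as.integer(k), subjects = subjects,
                 family_to_fold = fold_of), class = "fold_assignment")
}

#' Family-blocked cross-validated risk scores
#'
#' For each fold, fits the model on all other folds and predicts the
#' held-out subjects' linear predictors `eta_hat` — so no prediction ever
#' uses the subject or any relative of the subject.  Fixed effects are
#' taken at their posterior means; the genetic part applies marker-effect
#' posterior means to the held-out genotypes, centering with the training
#' allele frequencies.  A `gblup-grm` request is run in the equivalent
#' `gblup-brr` (ridge) parameterization, which carries marker effects and
#' so predicts unseen subjects without retraining.
#'
#' @param y binary outcome vector (subject order of `fixed_design`).
#' @param fixed_design covariate matrix including intercept.
#' @param genotypes complete dosage matrix / `genotype_matrix` (`NULL` for
#'   a covariates-only model).
#' @param folds a `fold_assignment` whose subjects match `y`'s order.
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_config()]; per-fold seeds are derived from its
#'   seed.
#' @return object of class `cv_result`: data.frame `scores`
#'   (`individual_id`, `fold`, `eta_hat`, `y`), per-fold AUCs, and the
#'   summary `auc_mean`, `auc_sd` (across folds) and `auc_pooled`.
#' @export
cross_validate <- function(y, fixed_design, genotypes = NULL, folds,
                           spec = model_spec(), mcmc = mcmc_config()) {
  stopifnot(inherits(folds, "fold_assignment"))
  sub <- folds$subjects
  n <- length(y)
  stopifnot(nrow(sub) == n, nrow(fixed_design) == n)
  if (spec$prior_family == "gblup-grm")
    spec$prior_family <- "gblup-brr"
  use_markers <- !is.null(genotypes) && spec$prior_family != "fixed-only"
  X <- if (use_markers) {
    if (inherits(genotypes, "genotype_matrix")) unclass_dosages(genotypes)
    else as.matrix(genotypes)
  } else NULL
  eta_hat <- rep(NA_real_, n)
  fold_auc <- rep(NA_real_, folds$k)
  skipped <- integer(0)
  for (f in seq_len(folds$k)) {
    test <- sub$fold == f
    train <- !test
    if (!any(test)) next
    if (length(unique(y[train])) < 2L) {
      warning("fold ", f, " skipped: training outcome single-class",
              call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    fold_mcmc <- mcmc
    fold_mcmc$seed <- mcmc$seed + 1000L * f
    fit <- fit_probit_wgr(y[train], fixed_design[train, , drop = FALSE],
                          if (use_markers) X[train, , drop = FALSE],
                          spec = spec, mcmc = fold_mcmc)
    eta_hat[test] <- predict(fit, fixed_design[test, , drop = FALSE],
                             if (use_markers) X[test, , drop = FALSE])
    if (length(unique(y[test])) == 2L)
      fold_auc[f] <- auc(y[test], eta_hat[test])
  }
  scored <- !is.na(eta_hat)
  structure(list(
    scores = data.frame(individual_id = sub$individual_id,
                        family_id = sub$family_id, fold = sub$fold,
                        eta_hat = eta_hat, y = y,
                        stringsAsFactors = FALSE),
    fold_auc = fold_auc,
    auc_mean = mean(fold_auc, na.rm = TRUE),
    auc_sd = stats::sd(fold_auc[!is.na(fold_auc)]),
    auc_pooled = if (length(unique(y[scored])) == 2L)
      auc(y[scored], eta_hat[scored]) else NA_real_,
    skipped_folds = skipped,
    prior_family = spec$prior_family), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: AUC %.3f +/- %.3f across folds (pooled %.3f)\n",
              x$prior_family, x$auc_mean, x$auc_sd, x$auc_pooled))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' The fraction of (case, control) pairs in which the case scores higher,
#' ties counted one half — computed with midranks, identical to exhaustive
#' pair counting.
#'
#' @param y binary 0/1 outcome, both classes present.
#' @param scores numeric risk scores, finite.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y, scores) {
  stopifnot(length(y) == length(scores), all(y %in% c(0, 1)),
            all(is.finite(scores)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both outcome classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One `(FPR, TPR)` point per distinct score threshold (scores sorted
#' decreasing), with endpoints `(0,0)` and `(1,1)`; the trapezoidal area
#' under the returned polyline equals [auc()].
#'
#' @inheritParams auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(y, scores) {
  stopifnot(length(y) == length(scores), all(y %in% c(0, 1)),
            all(is.finite(scores)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("ROC needs both outcome classes", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  last <- cumsum(rep(1, length(ss)))[!duplicated(ss, fromLast = TRUE)]
  # cumulative counts at each distinct-threshold boundary
  tp <- cumsum(ys)[last]; fp <- cumsum(1 - ys)[last]
  data.frame(threshold = c(Inf, ss[last]),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}
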
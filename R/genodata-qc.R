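#' Marker quality control
#'
#' Removes markers with minor allele frequency strictly below `maf_min` or
#' with a missing-call fraction strictly above `max_missing`.  Frequencies
#' are computed from observed (non-missing) calls, before any imputation.
#' A marker failing both rules is counted once, under the MAF reason.
#'
#' @param G a `genotype_matrix`.
#' @param maf_min MAF threshold (default 0.05, strict `<`).
#' @param max_missing missing-fraction threshold (default 0.10, strict `>`).
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (a `qc_report`: counts in, removed per reason, out, thresholds).
#' @export
qc_filter <- function(G, maf_min = 0.05, max_missing = 0.10) {
  X <- unclass_dosages(G)
  if (ncol(X) == 0L) stop("empty genotype matrix", call. = FALSE)
  miss <- colMeans(is.na(X))
  q <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(q, 1 - q)
  maf[is.nan(maf)] <- 0                       # fully missing marker
  fail_maf <- maf < maf_min
  fail_miss <- miss > max_missing
  keep <- !(fail_maf | fail_miss)
  report <- structure(list(
    n_markers_in = ncol(X),
    n_removed_maf = sum(fail_maf),
    n_removed_missing = sum(fail_miss & !fail_maf),
    n_markers_out = sum(keep),
    maf_min = maf_min, max_missing = max_missing), class = "qc_report")
  if (!any(keep))
    warning("all markers removed by QC", call. = FALSE)
  out <- genotype_matrix(X[, keep, drop = FALSE],
                         subject_ids = subject_ids(G),
                         marker_ids = marker_ids(G)[keep],
                         chrom = attr(G, "chrom")[keep],
                         pos = attr(G, "pos")[keep])
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE), "\n")
  invisible(x)
}

#' Randomly down-sample markers
#'
#' Keeps `round(fraction * p)` markers chosen uniformly without
#' replacement, preserving the original marker order.
#'
#' @param G a `genotype_matrix`.
#' @param fraction fraction of markers to keep, in (0, 1].
#' @param seed integer seed.
#' @return a `genotype_matrix`.
#' @export
downsample_markers <- function(G, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  p <- ncol(G)
  k <- round(fraction * p)
  set.seed(seed)
  keep <- sort(sample.int(p, k))
  X <- unclass_dosages(G)
  genotype_matrix(X[, keep, drop = FALSE], subject_ids = subject_ids(G),
                  marker_ids = marker_ids(G)[keep],
                  chrom = attr(G, "chrom")[keep],
                  pos = attr(G, "pos")[keep])
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing call with the marker's observed mean dosage
#' `2 q_hat_j`, which preserves the allele-frequency estimate of every
#' marker exactly.
#'
#' @param G a `genotype_matrix` with at least one observed call per marker.
#' @return a complete `genotype_matrix`.
#' @export
impute_missing <- function(G) {
  X <- unclass_dosages(G)
  if (!anyNA(X)) return(G)
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("fully missing marker(s): run qc_filter first (",
         paste(utils::head(marker_ids(G)[is.nan(mu)], 5), collapse = ", "),
         ")", call. = FALSE)
  na <- which(is.na(X), arr.ind = TRUE)
  X[na] <- mu[na[, 2]]
  genotype_matrix(X, subject_ids = subject_ids(G), marker_ids = marker_ids(G),
                  chrom = attr(G, "chrom"), pos = attr(G, "pos"))
}

#' Ancestry principal components from a marker subset
#'
#' Singular value decomposition of the column-centered dosage submatrix.
#' Constant marker columns are excluded with a warning.  The sign of each
#' component is fixed by making its largest-magnitude marker loading
#' positive.
#'
#' @param G a `genotype_matrix` without missing values.
#' @param marker_subset marker ids (or indices) used for the PCA; default
#'   all markers.
#' @param k number of components (default 2).
#' @return list of class `pc_scores`: `scores` (n x k matrix, columns
#'   `PC1..PCk`, centered), `loadings`, `explained` (variance fractions).
#' @export
compute_pcs <- function(G, marker_subset = NULL, k = 2L) {
  X <- unclass_dosages(G)
  if (anyNA(X)) stop("impute missing genotypes before PCA", call. = FALSE)
  if (!is.null(marker_subset)) {
    if (is.character(marker_subset)) {
      miss <- setdiff(marker_subset, marker_ids(G))
      if (length(miss))
        stop("unknown markers in subset: ", paste(miss, collapse = ", "),
             call. = FALSE)
      X <- X[, marker_subset, drop = FALSE]
    } else X <- X[, marker_subset, drop = FALSE]
  }
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant marker column(s) excluded from PCA",
            call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  if (k > min(dim(X)))
    stop("k exceeds min(n subjects, usable markers)", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  for (j in seq_len(k)) {                 # deterministic sign convention
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = loadings,
                 explained = sv$d[seq_len(k)]^2 / sum(sv$d^2)),
            class = "pc_scores")
}
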
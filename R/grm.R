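#' Estimated allele frequencies
#'
#' `q_hat_j` = mean observed dosage / 2, from non-missing calls.
#'
#' @param G a `genotype_matrix`.
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(G) {
  X <- unclass_dosages(G)
  q <- colMeans(X, na.rm = TRUE) / 2
  if (any(is.nan(q)))
    stop("fully missing marker(s): ",
         paste(utils::head(marker_ids(G)[is.nan(q)], 5), collapse = ", "),
         call. = FALSE)
  stats::setNames(q, marker_ids(G))
}

#' Genomic relationship matrix
#'
#' Cross-product of dosages centered at `2 q_hat_j`, divided by
#' `2 sum q_j (1 - q_j)` (VanRaden scaling), under which the expected
#' diagonal of unrelated, Hardy-Weinberg subjects is 1.  The
#' `"as-printed"` variant additionally divides by n, the number of
#' subjects, matching a formula that circulates with an extra 1/n factor;
#' it is retained for fidelity but shrinks all relationships toward zero
#' as the sample grows and is not recommended.
#'
#' @param G a `genotype_matrix` without missing values (impute first).
#' @param scaling `"vanraden"` (default) or `"as-printed"`.
#' @return object of class `grm`: the n x n matrix with attributes
#'   `sum2pq` (the denominator `2 sum q(1-q)`), `scaling`, and subject ids
#'   as dimnames.
#' @export
compute_grm <- function(G, scaling = c("vanraden", "as-printed")) {
  scaling <- match.arg(scaling)
  X <- unclass_dosages(G)
  if (ncol(X) < 1L) stop("need at least one marker", call. = FALSE)
  if (anyNA(X)) stop("GRM requires complete dosages (impute first)",
                     call. = FALSE)
  q <- colMeans(X) / 2
  sum2pq <- 2 * sum(q * (1 - q))
  if (sum2pq <= 0)
    stop("all markers monomorphic: GRM denominator is zero", call. = FALSE)
  Xc <- sweep(X, 2L, 2 * q)
  M <- tcrossprod(Xc) / sum2pq
  if (scaling == "as-printed") M <- M / nrow(X)
  dimnames(M) <- list(subject_ids(G), subject_ids(G))
  structure(M, sum2pq = sum2pq, scaling = scaling, class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d (%s scaling), mean diagonal %.3f\n",
              nrow(x), ncol(x), attr(x, "scaling"), mean(diag(x))))
  invisible(x)
}

#' Write a GRM as square TSV
#'
#' @param grm object from [compute_grm()].
#' @param path output file; subject ids form the header and first column.
#' @export
write_grm_tsv <- function(grm, path) {
  df <- data.frame(subject_id = rownames(grm), unclass(grm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Liability-scale genomic heritability from variance samples
#'
#' With the residual liability variance fixed at 1, each posterior sample
#' of the genomic variance maps to `h2 = sigma_u2 / (sigma_u2 + 1)`; the
#' summary is the posterior mean +/- SD of the per-sample ratios (the
#' mean-of-ratios convention, not the ratio of posterior means).
#'
#' @param sigma_u2_samples non-negative numeric vector of posterior draws.
#' @return list of class `h2_estimate`: `sigma_u2` and `h2`, each with
#'   `samples`, `mean`, `sd`.
#' @export
heritability <- function(sigma_u2_samples) {
  if (any(sigma_u2_samples < 0))
    stop("variance samples must be non-negative", call. = FALSE)
  h2 <- sigma_u2_samples / (sigma_u2_samples + 1)
  structure(list(
    sigma_u2 = list(samples = sigma_u2_samples,
                    mean = mean(sigma_u2_samples),
                    sd = stats::sd(sigma_u2_samples)),
    h2 = list(samples = h2, mean = mean(h2), sd = stats::sd(h2))),
    class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("genomic variance %.3f +/- %.3f; h2 (liability) %.3f +/- %.3f\n",
              x$sigma_u2$mean, x$sigma_u2$sd, x$h2$mean, x$h2$sd))
  invisible(x)
}
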
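#' Genotype dosage matrix
#'
#' A light S3 container: a numeric matrix of dosages (subjects x markers,
#' values in `[0, 2]`, NA allowed) with unique subject and marker ids as
#' dimnames and optional marker coordinates (1-based, as in PLINK .bim).
#'
#' @param dosages numeric matrix, subjects in rows.
#' @param subject_ids,marker_ids unique identifier vectors.
#' @param chrom,pos optional per-marker coordinates.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, subject_ids = rownames(dosages),
                            marker_ids = colnames(dosages),
                            chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- sprintf("snp%05d", seq_len(ncol(dosages)))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(marker_ids))
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2))
  if (length(bad))
    stop("dosages outside [0, 2] at entry ", bad[1], " (value ",
         dosages[bad[1]], ")", call. = FALSE)
  dimnames(dosages) <- list(subject_ids, marker_ids)
  structure(dosages, chrom = chrom, pos = pos, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d markers (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Extract the raw dosage matrix
#' @param G a `genotype_matrix`.
#' @return plain numeric matrix.
#' @export
unclass_dosages <- function(G) {
  x <- unclass(G)
  attr(x, "chrom") <- NULL; attr(x, "pos") <- NULL
  attr(x, "founder_freq") <- NULL
  x
}

#' Marker / subject identifiers
#' @param G a `genotype_matrix`.
#' @return character vector of ids.
#' @export
marker_ids <- function(G) colnames(G)

#' @rdname marker_ids
#' @export
subject_ids <- function(G) rownames(G)

# ---- TSV dosage ------------------------------------------------------------

#' Write genotypes as TSV dosage
#'
#' One row per subject; first column `subject_id`, then one column per
#' marker id.  Missing dosages written as NA.
#'
#' @param G a `genotype_matrix`.
#' @param path output file.
#' @export
write_dosage_tsv <- function(G, path) {
  df <- data.frame(subject_id = subject_ids(G), unclass_dosages(G),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes
#'
#' @param path file path: for `tsv-dosage` the TSV itself, for `plink-bed`
#'   the fileset prefix (or the .bed path).
#' @param format `"tsv-dosage"` or `"plink-bed"`.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("tsv-dosage", "plink-bed")) {
  format <- match.arg(format)
  switch(format,
         "tsv-dosage" = read_dosage_tsv(path),
         "plink-bed" = read_plink(sub("\\.bed$", "", path)))
}

read_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id")
    stop("dosage TSV must start with a subject_id column", call. = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric dosage values in ", path,
                           call. = FALSE)
  genotype_matrix(X, subject_ids = df$subject_id,
                  marker_ids = names(df)[-1])
}

# ---- PLINK .bed/.bim/.fam --------------------------------------------------
# SNP-major .bed: magic 0x6c 0x1b, mode 0x01; 2 bits per genotype, 4 per
# byte, subjects fastest.  2-bit codes: 00 = 2 copies of allele A1,
# 10 = 1 copy, 11 = 0 copies, 01 = missing.  Dosage = count of A1.

#' Write a PLINK .bed/.bim/.fam fileset
#'
#' Requires hard-call dosages (integers 0/1/2 or NA); real-valued dosages
#' cannot be represented in .bed and raise an error.
#'
#' @param G a `genotype_matrix`.
#' @param prefix output path prefix (writes prefix.bed/.bim/.fam).
#' @param pedigree optional pedigree data.frame supplying family and parent
#'   ids for the .fam file.
#' @export
write_plink <- function(G, prefix, pedigree = NULL) {
  X <- unclass_dosages(G)
  ok <- is.na(X) | X %in% c(0, 1, 2)
  if (!all(ok))
    stop("write_plink requires hard calls (0/1/2/NA); found dosage ",
         X[which(!ok)[1]], call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  chrom <- attr(G, "chrom"); pos <- attr(G, "pos")
  if (is.null(chrom)) chrom <- rep(1L, p)
  if (is.null(pos)) pos <- seq_len(p)
  bim <- data.frame(chrom = chrom, id = marker_ids(G), cm = 0, pos = pos,
                    a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (is.null(pedigree)) {
    fam <- data.frame(fid = subject_ids(G), iid = subject_ids(G),
                      pat = 0, mat = 0, sex = 0, phe = -9)
  } else {
    i <- match(subject_ids(G), pedigree$individual_id)
    fam <- data.frame(fid = pedigree$family_id[i], iid = subject_ids(G),
                      pat = ifelse(is.na(pedigree$father_id[i]), "0",
                                   pedigree$father_id[i]),
                      mat = ifelse(is.na(pedigree$mother_id[i]), "0",
                                   pedigree$mother_id[i]),
                      sex = 0, phe = -9)
  }
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # code per entry, subjects fastest within each SNP
  code <- matrix(1L, n, p)                       # 01 = missing
  code[!is.na(X) & X == 2] <- 0L
  code[!is.na(X) & X == 1] <- 2L
  code[!is.na(X) & X == 0] <- 3L
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  idx <- seq(1L, nbytes * 4L, by = 4L)
  bytes <- code[idx, , drop = FALSE] +
    4L * code[idx + 1L, , drop = FALSE] +
    16L * code[idx + 2L, , drop = FALSE] +
    64L * code[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' @param prefix fileset prefix.
#' @return a `genotype_matrix` with dosages as the count of allele A1.
#' @export
read_plink <- function(prefix) {
  for (ext in c(".bed", ".bim", ".fam"))
    if (!file.exists(paste0(prefix, ext)))
      stop("missing ", paste0(prefix, ext), call. = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  if (anyDuplicated(bim$id))
    stop("duplicate marker id in .bim: ",
         paste(unique(bim$id[duplicated(bim$id)]), collapse = ", "),
         call. = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           stringsAsFactors = FALSE)
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * p)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", prefix, ".bed",
         call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed supported", call. = FALSE)
  body <- as.integer(raw[-(1:3)])
  nbytes <- ceiling(n / 4)
  if (length(body) != nbytes * p)
    stop(".bed size inconsistent with .bim/.fam dimensions", call. = FALSE)
  # unpack 2-bit codes
  q1 <- body %% 4L
  q2 <- (body %/% 4L) %% 4L
  q3 <- (body %/% 16L) %% 4L
  q4 <- body %/% 64L
  codes <- matrix(rbind(q1, q2, q3, q4), nrow = nbytes * 4L)  # (4*nbytes) x p
  codes <- codes[seq_len(n), , drop = FALSE]
  X <- matrix(NA_real_, n, p)
  X[codes == 0L] <- 2; X[codes == 2L] <- 1; X[codes == 3L] <- 0
  genotype_matrix(X, subject_ids = as.character(fam[[2]]),
                  marker_ids = bim$id, chrom = bim$chrom, pos = bim$pos)
}
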
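test_that("dosage TSV and PLINK filesets round-trip exactly", {
  co <- small_cohort(n_families = 5, fam_range = c(3, 4), p = 10, seed = 4)
  G <- co$genotypes
  dir <- withr::local_tempdir()

  f <- file.path(dir, "g.tsv")
  write_dosage_tsv(G, f)
  back <- read_genotypes(f, "tsv-dosage")
  expect_equal(unclass_dosages(back), unclass_dosages(G))
  expect_identical(marker_ids(back), marker_ids(G))

  # PLINK round trip, including missing calls and n not divisible by 4
  X <- unclass_dosages(G)
  X[2, 3] <- NA; X[5, 1] <- NA
  G2 <- genotype_matrix(X, subject_ids = subject_ids(G),
                        marker_ids = marker_ids(G))
  prefix <- file.path(dir, "g")
  write_plink(G2, prefix, pedigree = co$pedigree)
  back2 <- read_genotypes(paste0(prefix, ".bed"), "plink-bed")
  expect_equal(unclass_dosages(back2), unclass_dosages(G2))
  expect_identical(marker_ids(back2), marker_ids(G2))
})

test_that("malformed genotype inputs raise named errors", {
  dir <- withr::local_tempdir()
  # bad magic bytes
  writeBin(as.raw(c(0x00, 0x01, 0x01, 0xff)), file.path(dir, "bad.bed"))
  writeLines("1\tsnp1\t0\t1\tA\tB", file.path(dir, "bad.bim"))
  writeLines("F1\tS1\t0\t0\t0\t-9", file.path(dir, "bad.fam"))
  expect_error(read_plink(file.path(dir, "bad")), "magic")

  # duplicate marker id in .bim
  G <- genotype_matrix(matrix(c(0, 1, 2, 2), 2, 2),
                       subject_ids = c("a", "b"),
                       marker_ids = c("snp1", "snp2"))
  write_plink(G, file.path(dir, "dup"))
  bim <- readLines(file.path(dir, "dup.bim"))
  writeLines(gsub("snp2", "snp1", bim), file.path(dir, "dup.bim"))
  expect_error(read_plink(file.path(dir, "dup")), "snp1")

  # out-of-range dosage in TSV
  writeLines(c("subject_id\tsnp1", "a\t2.4"), file.path(dir, "bad.tsv"))
  expect_error(read_genotypes(file.path(dir, "bad.tsv")), "\\[0, 2\\]")

  # fractional dosages cannot be written as .bed hard calls
  Gf <- genotype_matrix(matrix(c(0.5, 1), 2, 1))
  expect_error(write_plink(Gf, file.path(dir, "frac")), "hard calls")
})

test_that("QC removes markers by MAF and missingness with strict thresholds", {
  # marker 1: MAF 0.04 (fails); marker 2: 12% missing (fails);
  # marker 3: clean; marker 4: fails both, counted once
  n <- 50
  X <- cbind(c(rep(1, 4), rep(0, 46)),          # q = 0.04
             c(rep(NA, 6), rep(1, 44)),          # 12% missing
             rep(c(0, 1, 2), length.out = n),
             c(rep(NA, 6), rep(0, 43), 1))       # missing + rare
  G <- genotype_matrix(X, marker_ids = paste0("m", 1:4))
  res <- qc_filter(G)
  expect_identical(marker_ids(res$genotypes), "m3")
  expect_equal(res$report$n_markers_in, 4L)
  expect_equal(res$report$n_removed_maf, 2L)      # m1 and m4
  expect_equal(res$report$n_removed_missing, 1L)  # m2 only
  expect_equal(res$report$n_markers_out, 1L)
  expect_equal(res$report$n_markers_in - res$report$n_removed_maf -
                 res$report$n_removed_missing, res$report$n_markers_out)
})

test_that("QC passes clean data unchanged and is idempotent", {
  co <- small_cohort(n_families = 20, p = 50, seed = 8)
  res <- qc_filter(co$genotypes)
  once <- res$genotypes
  if (res$report$n_removed_maf + res$report$n_removed_missing == 0L)
    expect_equal(unclass_dosages(once), unclass_dosages(co$genotypes))
  twice <- qc_filter(once)
  expect_equal(unclass_dosages(twice$genotypes), unclass_dosages(once))
  expect_equal(twice$report$n_removed_maf, 0L)
  expect_equal(twice$report$n_removed_missing, 0L)
  # boundary: exactly-threshold markers are retained (strict inequalities)
  Xb <- cbind(c(rep(1, 5), rep(0, 45)),           # MAF exactly 0.05
              c(rep(NA, 5), rep(1, 45)))          # exactly 10% missing
  resb <- qc_filter(genotype_matrix(Xb))
  expect_equal(resb$report$n_markers_out, 2L)
})

test_that("marker down-sampling keeps the requested count in order", {
  co <- small_cohort(n_families = 10, p = 1000, seed = 2)
  G <- co$genotypes
  half <- downsample_markers(G, 0.5, seed = 3)
  expect_equal(ncol(half), 500L)
  expect_true(!is.unsorted(match(marker_ids(half), marker_ids(G))))
  expect_identical(marker_ids(downsample_markers(G, 0.5, seed = 3)),
                   marker_ids(half))
  expect_identical(marker_ids(downsample_markers(G, 1, seed = 1)),
                   marker_ids(G))
  expect_error(downsample_markers(G, 0), "fraction")
})

test_that("mean imputation fills missing calls and preserves frequencies", {
  X <- cbind(c(0, 2, NA), c(1, 1, 1), c(NA, 2, 2))
  G <- genotype_matrix(X)
  imp <- impute_missing(G)
  Xi <- unclass_dosages(imp)
  expect_equal(Xi[3, 1], 1.0)                      # mean of (0, 2)
  expect_equal(Xi[1, 3], 2.0)
  expect_false(anyNA(Xi))
  expect_equal(unname(colMeans(Xi) / 2),
               unname(allele_frequencies(G)))
  # identity on complete data
  full <- genotype_matrix(X[, 2, drop = FALSE])
  expect_identical(impute_missing(full), full)
  # fully missing marker
  Gbad <- genotype_matrix(cbind(c(NA, NA, NA), c(0, 1, 2)))
  expect_error(impute_missing(Gbad), "qc_filter")
})

test_that("principal components separate divergent populations", {
  set.seed(31)
  n1 <- 40; n2 <- 40; p <- 50
  X <- rbind(matrix(rbinom(n1 * p, 2, 0.1), n1, p),
             matrix(rbinom(n2 * p, 2, 0.9), n2, p))
  G <- genotype_matrix(X)
  pcs <- compute_pcs(G, k = 2)
  grp <- rep(c(1, 2), c(n1, n2))
  pc1 <- pcs$scores[, 1]
  expect_true(all(pc1[grp == 1] > 0) != all(pc1[grp == 1] < 0))
  expect_equal(sum(sign(pc1[grp == 1]) == sign(pc1[grp == 2])), 0)
  # orthogonality and centering within 1e-8
  expect_lt(abs(sum(pcs$scores[, 1] * pcs$scores[, 2])), 1e-8)
  expect_lt(max(abs(colMeans(pcs$scores))), 1e-8)
  expect_true(all(pcs$explained >= 0 & pcs$explained <= 1))
})

test_that("degenerate PCA inputs are guarded", {
  X <- cbind(rep(1, 10), rbinom(10, 2, 0.5), rbinom(10, 2, 0.5))
  G <- genotype_matrix(X)
  expect_warning(compute_pcs(G, k = 2), "constant")
  expect_error(suppressWarnings(compute_pcs(G, k = 5)), "k exceeds")
  expect_error(compute_pcs(G, marker_subset = c("nope"), k = 1), "nope")
})
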
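#!/usr/bin/env Rscript
# Genotype quality control and relationship structure: remove markers
# with MAF < 0.05 or > 10% missing calls, mean-impute the remainder,
# optionally down-sample markers, then compute the genomic relationship
# matrix and two ancestry principal components.  The GRM diagnostics
# (diagonal near 1, parent-offspring entries near 0.5) verify that the
# marker panel recovers the pedigree's relatedness.

library(probitWGR)

G <- read_genotypes("results/cohort/genotypes.tsv", "tsv-dosage")
ped <- read.delim("results/cohort/pedigree.tsv")

qc <- qc_filter(G, maf_min = 0.05, max_missing = 0.10)
cat("QC report: "); print(qc$report)
G <- impute_missing(qc$genotypes)

grm <- compute_grm(G)
write_grm_tsv(grm, "results/grm.tsv")
cat(sprintf("GRM: mean diagonal %.3f\n", mean(diag(grm))))

idx <- setNames(seq_len(nrow(ped)), ped$individual_id)
kid <- which(!is.na(ped$father_id))
po <- mean(grm[cbind(idx[ped$father_id[kid]], kid)])
cat(sprintf("mean parent-offspring relationship: %.3f (pedigree: 0.5)\n",
            po))

pcs <- compute_pcs(G, k = 2)
write.table(data.frame(individual_id = rownames(pcs$scores), pcs$scores),
            "results/pcs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of genotypic variance\n",
            100 * pcs$explained[1], 100 * pcs$explained[2]))
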
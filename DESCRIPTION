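Package: probitWGR
Title: Bayesian Whole-Genome Regression for Binary Traits in Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gibbs samplers for probit-link whole-genome regression of a
    binary disease outcome on dense SNP genotypes under Bayes A, Bayes C-pi,
    Bayesian LASSO and G-BLUP (Bayesian ridge) priors, with flat-prior
    non-genetic covariates and the residual variance fixed at one on the
    liability scale.  Includes a gene-dropping simulator for two-generation
    family cohorts with a liability-threshold phenotype of configurable
    heritability, genotype quality control and PLINK input/output, genomic
    relationship matrices and liability-scale genomic heritability, and
    family-blocked cross-validation evaluated with ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
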
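Package: liabh2
Title: Dual-Track Heritability Estimation for Binary Traits Under the
    Liability-Threshold Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates narrow-sense heritability of a binary (disease)
    phenotype by two complementary tracks: a genotype-based track that
    builds genetic relationship matrices from SNP dosages and fits
    variance components by average-information REML (whole-autosome,
    per-chromosome and per-SNP partitions) with liability-scale
    transformation under case-control ascertainment, cross-checked by
    phenotype-correlation genotype-correlation (PCGC) regression; and a
    pedigree-based track that fits a Bayesian liability-threshold
    ("animal") probit model by Gibbs sampling on the numerator
    relationship matrix. Includes seeded synthetic-data generators for
    case-control GWAS genotypes and multi-generation pedigrees under the
    additive liability model, SNP and sample quality control with
    genomic-control inflation statistics, conversion of heritability to
    sibling recurrence risk, and GCTA- and PLINK-compatible file
    readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
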
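Package: cardiostrat
Title: Genotype-Stratified Single-Nucleus RNA-Seq Analysis of Cardiomyopathy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genotype-stratified analysis of
    single-nucleus RNA-seq from multi-patient, two-chamber heart cohorts:
    a seeded synthetic-data generator with a ground-truth ledger,
    compositional testing of cell-type abundances via centered log-ratio
    transforms and covariate-adjusted linear models, pseudobulk
    negative-binomial differential expression with moderated dispersion
    estimation, ligand-receptor interaction probabilities with a
    permutation null, and a graph attention network for multinomial
    genotype classification with leakage-safe patient-level aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
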
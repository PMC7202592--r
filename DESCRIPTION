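Package: metbc
Title: Genomic Enrichment Analysis of Metastatic Breast Cancer Panel Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing targeted panel sequencing cohorts of breast
    tumors biopsied from local disease, lymph nodes and distal metastases.
    Provides covariate-adjusted enrichment scanning of per-gene alteration
    features with max-statistic permutation control of the family-wise error
    rate, random-forest imputation of estrogen-receptor and histological
    subtype, ESR1 ligand-binding-domain hotspot analysis, gene-masked
    tissue-of-origin classifiers for misdiagnosis detection, rule-based
    extraction of hormone-receptor status from pathology report text, and
    age-trend diagnostics for clonal hematopoiesis. A configurable synthetic
    cohort generator with ground-truth labels supports calibration and
    property testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
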
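Package: hlbc
Title: Integrative Genomic and Transcriptomic Profiling of HER2-Low Breast Carcinomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative analysis of HER2-low breast carcinoma
    (HLBC) cohorts profiled with targeted DNA panels and targeted gene
    expression assays. Implements panel-based mutation statistics (tumor
    mutational burden, microsatellite instability fraction, variant allele
    frequency summaries, mutational-signature refitting by non-negative
    least squares), stratified matched-cohort construction with
    differential-mutation testing, gene-set global significance scores
    (GSS/dGSS) on covariate-adjusted differential expression, consensus
    non-negative matrix factorization class discovery with
    cophenetic-coefficient rank selection and exclusion of clusterings that
    recapitulate PAM50 intrinsic subtypes, and rule-table annotation of
    clinically actionable alterations. A seeded synthetic-cohort generator
    emulates the data structure of such studies for testing and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    mclust,
    pracma,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
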
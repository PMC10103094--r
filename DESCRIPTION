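Package: ehrcausal
Title: Propensity-Weighted Causal Effect Estimation from EHR Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Emulates target trials of drug exposure on a binary
    hospitalization outcome from OMOP-like electronic health record
    snapshots. Estimates average treatment effects by inverse probability
    of treatment weighting with two confounder representations: a
    high-dimensional one-hot covariate vector fitted with sparse (L1)
    logistic regression, and an averaged medical-concept graph embedding
    fitted with random forest. Includes stratified bootstrap confidence
    intervals with per-replicate propensity refitting, negative-control
    outcome validation, user-versus-nonuser and active-comparator cohort
    designs, covariate balance diagnostics, and a synthetic EHR generator
    with stored potential outcomes for exact parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
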
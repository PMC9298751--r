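Package: altsynergy
Title: Additive-Scale Drug-Drug Interaction Screening for Abnormal ALT Elevation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens pairs of co-prescribed drugs for synergistic (additive-scale)
    interaction on abnormal elevation of serum alanine aminotransferase (ALT)
    in longitudinal electronic health records. Builds a case-control cohort
    anchored on repeated liver-function tests, engineers binary drug-exposure
    features with pairwise product terms and therapeutic-class rollups, fits
    multiple logistic regression, L1-penalized (LASSO) logistic regression and
    gradient-boosted tree classifiers, and estimates the relative excess risk
    due to interaction (RERI) with bootstrap-percentile confidence intervals
    and a dual-criterion synergy call. Includes a synthetic EHR generator with
    planted interaction effects so the full pipeline is testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    pROC,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
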
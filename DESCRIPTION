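Package: spadgdd
Title: Phenology-Aligned SPAD Diagnosis of Rice Nitrogen Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing rice nitrogen status from multi-leaf SPAD
    (chlorophyll meter) readings aligned on a physiological time axis.
    Computes growing degree days (GDD) from daily temperature extremes,
    the nitrogen nutrition index (NNI) via a critical nitrogen dilution
    curve, and compares SPAD/GDD feature formulations and simplified
    measurement protocols under leakage-safe grouped cross-validation
    (PLS, SVR, random forest, gradient boosting). Provides residual-versus-GDD
    bias diagnostics, out-of-fold Shapley feature attributions for tree
    ensembles (exact path-dependent TreeSHAP), LOWESS smoothing of per-sample
    mid-canopy importance shares along GDD with group-bootstrap confidence
    bands, and crossover-point estimation. Includes a synthetic multi-experiment
    field-trial generator with a configurable ground-truth importance crossover
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    e1071,
    randomForest,
    xgboost,
    mixOmics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
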
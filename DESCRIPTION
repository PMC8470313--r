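Package: posturescreen
Title: Pathology-Independent Screening of Spinal Posture Data
Version: 0.1.0
Authors@R:
    person("posturescreen", "developers", email = "dev@posturescreen.invalid",
           role = c("aut", "cre"))
Description: Tools for pathology-independent screening of rasterstereographic
    spinal posture measurements. A one-class support vector machine is trained
    on healthy subjects only, its decision scores are calibrated into outlier
    probabilities with Platt scaling, and predictions are explained per subject
    with a local surrogate-model (LIME-style) explainer. The package includes a
    synthetic-cohort generator that creates healthy surrogate data and
    pathology classes of controlled silhouette separation by shifting a single
    principal component, isolation-forest cleaning of the healthy training
    pool, subject-grouped cross-validation that prevents leakage of repeated
    measurements, a calibrated random-forest binary baseline, and an
    evaluation suite (F1, Matthews correlation coefficient, Brier Skill
    Score, confusion matrices, subject-level probability aggregation).
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
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
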
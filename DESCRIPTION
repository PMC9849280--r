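Package: ppgbp
Title: Estimating Changes in Blood Pressure from PPG and ECG Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for estimating changes in systolic, mean and
    diastolic blood pressure from morphological features of the
    photoplethysmogram (PPG) and single-lead electrocardiogram (ECG).
    Includes a synthetic-cohort generator emulating a vasoconstrictor
    (phenylephrine) infusion protocol, zero-phase signal filtering, pulse
    segmentation with beat normalisation, Pan-Tompkins QRS detection,
    fiducial-point detection, four-Gaussian pulse decomposition by bounded
    least squares, a 77-column feature library (PPG/VPG/APG morphology,
    Gaussian indices, principal components, ECG complexity and entropy
    measures, demographics), cubic smoothing-spline interpolation of sparse
    cuff readings, hybrid calibration, collinearity removal by variance
    inflation factors, LASSO+OLS and random-forest regression evaluated in
    nested leave-one-subject-out cross-validation, and Shapley-value feature
    importance with a cross-fold ranking coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    glmnet,
    ranger,
    zoo,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
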
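Package: resttask
Title: Sparse Ensemble Prediction of Individual Task Activation Maps from
    Resting-State Functional Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individual differences in task-evoked brain activation
    from resting-state functional modes. Individual rest-mode and task
    contrast maps are residualised against training-fold group averages,
    recording per-map activation amplitudes; the residual (variation) maps
    are modelled by a per-subject multiple-regression baseline model, a
    cross-subject ICA-reduced per-voxel Lasso (sparse) model, and a
    per-voxel linear ensemble stacker, with a separate linear model for
    activation amplitude. Includes a synthetic-cohort generator with full
    ground truth, dual regression of group spatial templates, and the
    evaluation suite (subject-by-subject correlation matrices, prediction
    accuracy, Fisher-z discriminability, identification rate, variability-map
    correspondence, test-retest reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    glmnet,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
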
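Package: stanet
Title: Spatio-Temporal Aggregation Networks for Resting-State fMRI
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies subjects in small, imbalanced resting-state fMRI
    cohorts (e.g. depressed patients versus healthy controls) with a
    spatio-temporal aggregation pipeline: group independent component
    analysis with stability-based restart matching, spatial-similarity
    regression against a resting-state network atlas, multi-scale 2D
    convolutional feature fusion, SMOTE balancing of training folds, and
    a Fourier-augmented gated recurrent classifier with attention
    pooling and adaptively weighted branch outputs, evaluated by
    subject-level stratified k-fold cross-validation. Includes a
    synthetic-cohort generator so the full pipeline can be exercised and
    tested without any imaging download, plus NIfTI/CSV/JSON readers and
    writers and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
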
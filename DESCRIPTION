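Package: PocketActivity
Title: Activity Recognition from Pocket-Worn Phone Accelerometers in
    Healthy and Parkinsonian Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for recognizing five everyday activities (walking,
    standing, holding, sitting, not wearing) from triaxial accelerometer
    recordings of a phone carried in a front pocket. Covers resampling of
    variable-rate signals to a uniform 20 Hz, segmentation into 10 s clips,
    pocket-orientation sign-flip augmentation, a 178-value time-series
    feature extractor, RBF-kernel support vector machine and L1-regularized
    multinomial logistic classifiers, and three cross-validation regimes
    (systematic 10-fold, leave-one-subject-out, and cross-population
    transfer from healthy to parkinsonian movement). A seeded synthetic
    cohort generator emulates healthy and parkinsonian phone-in-pocket
    signals so every stage is testable without recorded subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    glmnet,
    data.table,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
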
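Package: drnrf
Title: Mental Fatigue Detection from Facial Landmarks with a Stacked
    Residual-Network and Random-Forest Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects an operator's mental fatigue level on a simplified
    five-level Karolinska Sleepiness Scale from 68-point facial-landmark
    coordinates. Provides the full pipeline: dataset input/output and
    landmark feature conventions, three-sigma outlier repair with
    neighbour-mean imputation, frame relativisation and min-max
    normalisation, Monte-Carlo recursive feature elimination with
    cross-validation (MC-RFECV) stability selection, a stacked classifier
    combining out-of-fold deep-residual-network probabilities with a
    random-forest meta-learner (DRN-RF), reference baselines (ANN, GBM,
    KNN, RF), an evaluation protocol with repeated trials and one-way
    ANOVA comparisons, and a synthetic landmark-data generator with
    recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ranger,
    randomForest,
    xgboost,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
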
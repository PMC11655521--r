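Package: dropcurve
Title: Learning-Curve Sample-Size Planning for Dropout Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the minimal dataset size needed to train
    reliable dropout-prediction models for digital (mental) health
    interventions. Provides a seeded synthetic cohort generator calibrated
    to target discriminability (population AUC) per feature group under an
    equicorrelated binormal model, a repeated stratified-subsampling
    learning-curve harness with 10-fold grid-search cross-validation over
    six classifier families, from-scratch AUC inference (Mann-Whitney
    midranks, paired DeLong test, Hanley-McNeil variance), overfitting and
    fold-variance diagnostics, and Kneedle knee-point detection of
    learning-curve convergence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    nnet,
    jsonlite,
    yaml,
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
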
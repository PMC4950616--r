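Package: treeshift
Title: Ensemble Species Distribution Modelling and Climate-Change
    Habitat Vulnerability Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits multi-technique, multi-repetition species distribution
    model ensembles, combines projections into an AUC-weighted consensus,
    binarizes habitat suitability at the threshold jointly maximizing
    sensitivity and specificity, and classifies each grid cell of a
    species' baseline range as unsuitable, less suitable, or persistent
    habitat under an ensemble of future climate simulations, with
    per-cell agreement values and regional summaries. Includes
    change-field (delta) climate downscaling with triangle-based linear
    interpolation, k-means selection of representative climate
    simulations, and a synthetic-landscape generator with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    rpart,
    nnet,
    randomForest,
    xgboost,
    glmnet,
    mclust,
    interp,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
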
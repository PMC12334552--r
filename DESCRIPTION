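Package: sdmrisk
Title: Ensemble Species Distribution Models and Climate-Driven Red List
    Reassessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing the extinction risk of
    range-restricted plants under climate change. Fits an ensemble of five
    presence/pseudo-absence habitat-suitability algorithms (GLM, CTA, GBM,
    RF, MAXENT-style regularized logistic) with repeated 70/30 validation,
    AUC/TSS gating and four ensemble combiners (mean, median, committee
    averaging, TSS-weighted mean); binarizes suitability with a fixed
    cutoff plus a Fisher-Jenks natural-breaks diagnostic; computes
    retained/lost/gained habitat accounting on an area-true
    latitude/longitude grid; derives IUCN Criterion-B metrics (EOO, AOO,
    locations) and applies a climate-driven Red List reclassification
    decision table; and overlays habitat with protected-area masks for gap
    analysis. A virtual-species simulator generates spatially
    autocorrelated landscapes, Gaussian-niche species, occurrence samples
    and future climate scenarios so the whole pipeline is testable with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    glmnet,
    randomForest,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    pROC,
    optparse
Config/testthat/edition: 3
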
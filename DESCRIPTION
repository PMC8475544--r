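Package: benthosdm
Title: Ensemble Species Distribution Models for Deep-Sea Benthic Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline for presence-background
    habitat suitability modeling of deep-water corals and sponges. Derives
    bathymetric terrain predictors (slope, aspect indices, curvatures,
    surface-ratio roughness, topographic position index, vector ruggedness
    measure), upscales depth-layered oceanographic fields to the seafloor,
    builds sampling-bias-corrected pseudoabsence sets from a kernel density
    estimate of survey effort, fits boosted regression trees, binomial
    additive models, a penalized maximum-entropy model, and random forests,
    combines them into an AUC-weighted ensemble, and evaluates everything with
    Monte-Carlo cross-validation (AUC/TSS), per-cell uncertainty maps,
    response curves, permutation variable contributions, and geomorphology
    summaries. A synthetic seascape generator with known niches makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mgcv,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
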
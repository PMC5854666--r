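Package: refugia
Title: Ensemble Niche Modelling of Climate-Change Impacts on Protected-Area Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess potential climate-change impacts on the biodiversity
    of a protected-area network with ensemble ecological niche models. Simulates
    a synthetic study system (gridded two-period climate, virtual species with
    known niches, protected areas, nested regions), screens collinear predictors,
    fits per-species model ensembles on presence/pseudo-absence data, projects
    and binarizes suitability under reference and future climates, overlays
    projections on protected areas, and computes species gain, loss, turnover,
    richness, representativity at nested spatial scales, and per-species
    protected-range change, with paired Wilcoxon comparisons across periods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    glmnet,
    rpart,
    randomForest,
    class,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
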
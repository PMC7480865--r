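Package: podomapr
Title: Ensemble Environmental Suitability Mapping and Population at Risk
    for Podoconiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of an ensemble
    species-distribution-modelling pipeline for podoconiosis, a tropical
    lymphedema linked to irritant volcanic clay soils. From a weighted
    presence/absence/pseudo-absence training table and a stack of gridded
    environmental covariates, the pipeline fits six suitability learners
    (GLM, GAM, GBM, ANN, MARS, RF) over repeated stratified 80/20 splits,
    gates replicates on held-out AUC and true skill statistic, combines
    survivors into an AUC-weighted mean suitability surface with
    per-cell uncertainty bounds, validates with spatial block
    cross-validation, optimises the presence threshold, and converts the
    binary occurrence map into population-at-risk estimates with
    uncertainty intervals, disease co-suitability overlap tables and
    implementation-unit classifications. A seeded synthetic-scenario
    generator produces complete desk-scale inputs (covariates, truth
    surface, surveys, evidence scores, population, zones, a second
    binary risk layer) so every stage is testable without downloads.
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
    jsonlite,
    mgcv,
    nnet,
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
    tiff,
    withr
Config/testthat/edition: 3
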
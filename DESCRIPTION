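Package: firbiomass
Title: Stand-Level Biomass Models for Chinese Fir from Airborne LiDAR Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An area-based workflow for estimating component biomass of Chinese fir
    (Cunninghamia lanceolata) stands from airborne LiDAR point clouds. Provides a
    synthetic generator for age-structured plots and plot-level point clouds with
    known ground truth, allometric partitioning of above-ground biomass into trunk,
    bark, branch and leaf components, extraction of 57 per-plot point-cloud metrics
    (height percentiles, cumulative height percentiles, height statistics, intensity
    percentiles, canopy cover, leaf area index), two-stage variable screening
    (Pearson significance then variance-inflation-factor pruning), and four model
    families per biomass component: nonlinear base forms, nonlinear mixed-effects
    models with age-group random effects selected by AIC over all random-effect
    combinations, dummy-variable models with backward t-test pruning, and random
    forests. Includes a stratified 70/30 evaluation with bias-decomposed RMSE and
    total relative error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    minpack.lm,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
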
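Package: middensdm
Title: High-Resolution Distribution Modelling of Red Squirrel Middens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end workflow for predicting red squirrel (Tamiasciurus
    hudsonicus) midden occurrence at 3 x 3 m resolution from LIDAR-derived
    canopy and terrain rasters and Euclidean-distance layers to human
    disturbance features. Provides a synthetic landscape generator with known
    midden response functions, LIDAR point-cloud gridding (DEM, canopy height,
    canopy density, slope, aspect), distance-transform predictors,
    presence/pseudo-absence sampling with class-balancing weights, stochastic
    gradient-boosted classification trees producing a relative index of
    occurrence (RIO) with variable importance and partial dependence,
    inverse-distance-weighted prediction surfaces, percentile-based occupancy
    classification, and midden-based density, territory and population
    estimates with independent-point validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
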
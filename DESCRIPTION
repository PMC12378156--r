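Package: canopyscale
Title: Two-Stage Forest Canopy Closure Estimation from LiDAR Footprints to Regional Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates forest canopy closure (FCC) wall-to-wall from sparse
    spaceborne-LiDAR footprints in two stages. At the footprint scale, small
    field-plot samples train KNN, random-forest and gradient-boosting
    regressors whose hyperparameters are tuned by Gaussian-process Bayesian
    optimization and scored by leave-one-out cross-validation. At the regional
    scale, footprint predictions train a geographically weighted regression
    (GWR) on multi-source raster covariates (vegetation indices, SAR
    backscatter transforms, GLCM textures, terrain derivatives) with
    AICc-minimizing golden-section bandwidth selection, producing an FCC map
    with local diagnostics. A seeded synthetic-scene generator supplies every
    input, so the whole chain is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    ranger,
    xgboost,
    lhs,
    car,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
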
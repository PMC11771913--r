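Package: crashspot
Title: Crash Hotspot Detection and Bayesian Spatial Probit Modelling of
    Injury Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage geospatial and econometric analysis of road-crash
    injury severity for older drivers. Stage one identifies crash hotspots
    from point-referenced crash locations with a density-based clustering
    algorithm (DBSCAN) and a radius/density sensitivity sweep, exporting
    hotspot polygons. Stage two models the binary injury outcome (property
    damage only versus injury or fatality) with a Bayesian spatial lag
    binary probit estimated by Markov chain Monte Carlo with latent-variable
    augmentation and a Metropolis-Hastings step for the spatial dependence
    parameter, compared against a non-spatial probit by the deviance
    information criterion. A synthetic-data module generates clustered point
    patterns and crash tables from a spatial lag probit data-generating
    process with known ground truth, so the full pipeline is testable
    without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
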
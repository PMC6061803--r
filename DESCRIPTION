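Package: effconn
Title: Sensor-Space Effective Connectivity and Network Efficiency for MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pipeline for resting-state MEG sensor-space effective
    connectivity analysis: planar-gradiometer root-mean-square combination,
    principal-component reduction, stable multivariate autoregressive (MVAR)
    modelling with Vieira-Morf estimation and BIC order selection,
    frequency-resolved partial directed coherence, proportional-threshold
    directed graphs and local-efficiency maps, scalp-by-frequency
    nonparametric permutation statistics with cluster-level correction, and
    linear support-vector classification.  Includes a source-to-sensor
    validation simulator (MVAR source networks, smooth gain-matrix forward
    projection, controlled sensor noise) so that every stage is testable on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
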
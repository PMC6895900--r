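Package: stcox
Title: Spatial- and Temporal-Smoothed Cox Proportional Hazards Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits location- and period-specific Cox proportional hazards
    models to survival data collected over a grid of spatial sites and
    consecutive time intervals, smoothing the per-cell regression
    coefficients with a fused quadratic penalty over adjacent time
    intervals and an inverse-distance-weighted quadratic penalty over
    pairs of locations. Estimation uses an outer Taylor-surrogate
    Newton scheme with a diagonal curvature approximation and inner
    block-wise closed-form updates cycled Gauss-Seidel style over all
    (location, period) cells. Includes V-fold cross-validation for the
    two penalty weights, stratified nonparametric bootstrap standard
    errors, unpenalized separate and pooled comparators, and a survival
    panel simulator with controllable coefficient surfaces and
    censoring rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
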
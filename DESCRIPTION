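Package: ccdlnm
Title: Distributed Lag Non-Linear Models in a Time-Stratified Case-Crossover Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate non-linear and delayed (distributed lag) effects of
    daily temperature on mortality within a time-stratified case-crossover design.
    Builds cross-basis design matrices combining natural cubic spline or
    double-threshold ("hockey stick") exposure bases with spline lag structures,
    fits overdispersed (quasi-Poisson) stratified models and their conditional
    Poisson equivalents, searches cold/hot temperature thresholds by residual
    deviance over a grid, and summarises fitted models as relative-risk surfaces,
    lag curves and cumulative effects with delta-method confidence intervals.
    Includes a synthetic daily-series generator with configurable true
    temperature-lag effect surfaces for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
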
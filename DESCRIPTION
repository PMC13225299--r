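Package: darkadaptr
Title: Modeling and Diagnostics for Two-Color Fundus-Controlled Dark
    Adaptometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for fundus-controlled two-color dark
    adaptometry. Fits the biphasic cone/rod threshold-recovery model to
    cyan/red stimulus time series, derives rod intercept time (with
    60-minute censoring), cone threshold and final rod threshold per
    retinal locus, builds age- and eccentricity-adjusted normative limits
    from healthy eyes via linear mixed models, expresses patient outcomes
    as deviations from those limits, and quantifies diagnostic accuracy
    with covariate-adjusted ROC curves. Includes a synthetic-cohort and
    adaptive-staircase session simulator so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
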
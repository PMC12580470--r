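Package: dielshift
Title: Temporal Displacement of Mammal Activity from Paired Camera-Trap
    Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for camera-trap studies of wildlife temporal
    displacement under combined hunting and recreation disturbance.
    Independence-filters detection streams, computes relative abundance
    indices and a trail-use index with location-level nonparametric
    bootstrap confidence intervals, classifies hunting-effort strata from
    monthly cull calendars, converts clock time to sunrise/sunset-anchored
    solar time via a built-in NOAA-style solar ephemeris, estimates
    circular (von Mises kernel) activity densities over a
    disturbance-stratified subset scheme, and fits an overdispersed
    beta-binomial nocturnality regression with three-way effort by
    placement by covariate interactions. Includes a synthetic-data
    generator with known circadian ground truth so the whole pipeline runs
    and is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
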
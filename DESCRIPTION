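Package: chitrack
Title: Synthetic Coded Hemodynamic Imaging of Jugular Venous Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for camera-based jugular venous
    monitoring. Generates synthetic near-infrared neck video from a layered
    Beer-Lambert tissue model with sex-specific anatomy, extracts jugular venous
    attenuation (JVA) by photoplethysmography anticorrelation mapping, simulates
    ultrasound cross-sectional area (CSA) measurement, and runs the statistical
    battery comparing JVA with CSA across head-down tilt and lower-body negative
    pressure: linear mixed models with sex-by-level interactions, repeated-measures
    correlation, per-participant regressions, rank-sum slope comparisons and
    reliability stratification by CSA change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    signal,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
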
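Package: pmcal
Title: Calibration of Wearable Optical Particulate Monitors and
    Breathing-Zone Exposure Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calibrating low-cost wearable optical particulate
    matter (PM) monitors against a slow-response reference instrument and
    for analysing breathing-zone PM exposure trials. Detects quasi-steady-
    state chamber intervals by rolling coefficient of variation, estimates
    the reference instrument's response lag by cross-correlation, fits
    per-unit and averaged-unit ("universal") linear calibrations with
    precision diagnostics (pooled inter-unit CV, pairwise correlations),
    applies calibrations to raw field logs, computes windowed exposure
    averages, and fits lognormal repeated-measures mixed models for
    treatment and measurement-duration effects with back-transformed
    least-squares means. Seeded generators emulate both the co-location
    chamber experiment and a cross-over feed trial so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
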
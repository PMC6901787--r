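Package: breathscore
Title: Weighted Digital Analysis of Exhaled Volatile Organic Compound Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for breath volatilomics biomarker discovery from two-dimensional
    gas chromatography (GCxGC) peak tables: retention-time-window feature alignment,
    breathing-circuit background subtraction, internal-standard normalization,
    dual-axis ROC/AUC candidate screening, and weighted digital analysis (WDA)
    breath-score modelling with leave-one-subject-out forward selection. Includes a
    longitudinal hyperoxia exposure-study simulator (planted marker compounds,
    internal standard, arterial blood gas trajectories) so the full pipeline is
    testable end to end, and evaluation utilities for PaO2/FiO2-defined pulmonary
    oxygen toxicity outcomes: empirical ROC curves, subject-level bootstrap
    confidence intervals, per-timepoint elevation tests and breath-score-to-P/F
    latency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
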
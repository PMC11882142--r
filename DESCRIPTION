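Package: mazepe
Title: Behavioral and Neural Prediction-Error Analyses for Probabilistic
    Spatial Threat Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for a probabilistic spatial threat-learning
    task in which mice traverse a square maze between two reward sites via
    paths carrying different air-puff probabilities. Segments position
    tracking into laps, derives approach/reaction speed metrics and
    median-split threat-expectation labels, quantifies lap-history dependence
    of path choice (post-threat switching and lagged choice-outcome
    correlations), aligns calcium traces to threat-site entry, z-normalizes
    event-locked responses per lap type, and classifies cells as signed or
    unsigned aversive prediction-error coders. Includes a Rescorla-Wagner
    softmax maze agent and a GCaMP-like transient generator that provide
    ground truth for every stage, plus the repeated-measures/mixed ANOVA
    toolbox (with Greenhouse-Geisser correction) used for group inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
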
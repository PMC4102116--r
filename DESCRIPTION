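Package: bistab
Title: Detection of Bistable Taxa and Tipping Points in Microbiome
    Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects alternative stable states ("tipping elements") in
    cross-sectional microbial abundance profiles using potential analysis:
    kernel density estimation is inverted through the stationary
    Fokker-Planck relation to a pseudo-potential whose minima mark stable
    states.  Provides bootstrap bimodality scoring, tipping-point
    estimation, prediction-strength validation, temporal-stability
    analysis of longitudinal follow-up (intermediate-range instability and
    Kaplan-Meier state survival), community-level summaries (state
    combination census, covariation screening, ordination, clustering with
    Jensen-Shannon dissimilarity), logistic-regression association tests
    against host metadata, and a synthetic cohort generator with known
    ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    e1071,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
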
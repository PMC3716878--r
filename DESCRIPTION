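Package: vpcoupling
Title: Visuo-Proprioceptive Coupling in Tool Use: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coupling of visually sensed cursor
    direction and proprioceptively felt hand direction under a visuomotor
    rotation paradigm. Provides a generative simulator of the three-stroke
    aiming task (12 feedback rotations x 2 explicit judgment types x 6
    repetitions per participant), a geometric implicit measure of the felt
    hand direction from return-stroke endpoints, regression-based
    proportional-bias estimation with two-level iterative outlier screening,
    trial-history (sequential-effect) classification and subset-bias
    analysis, mixed-design ANOVAs, and the weighted-average coupling model's
    variance-reduction mathematics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
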
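Package: greenkeeper
Title: Decision Support for Precision Nitrogen Management on Sand-Based Putting Greens
Version: 0.1.0
Authors@R:
    person("Green", "Keeper", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements and compares four nitrogen fertilization decision
    strategies for creeping bentgrass putting greens: temperature-based
    growth-potential dosing, an experience-based biweekly schedule, a
    red-edge vegetation index (NDRE) threshold rule, and a regression-forest
    growth model that converts predicted clipping yield into
    clipping-replacement nitrogen doses. A seeded virtual putting-green
    simulator (stochastic weather, soil nitrogen pool, clipping yield, NDRE,
    visual quality) allows the strategies to be run, audited, and compared
    end-to-end without field data, and an evaluation module computes
    nitrogen budgets, nitrogen use efficiency, prediction-ratio statistics,
    and quality summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
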
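Package: maic2s
Title: Two-Stage Matching-Adjusted Indirect Comparison for Anchored
    Population Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Anchored population-adjusted indirect treatment comparisons
    when individual patient data are available for one trial and only
    published aggregate data for the other.  Implements matching-adjusted
    indirect comparison (MAIC) via method-of-moments trial-assignment
    odds weights, its two-stage extension (2SMAIC) that rescales the odds
    weights by inverse-probability-of-treatment weights from a propensity
    model, 95th-percentile weight truncation of either estimator, and
    non-parametric bootstrap inference.  A simulation engine generates
    paired index/competitor randomized trials under a factorial grid of
    sample sizes and covariate-overlap settings and summarizes estimator
    performance (bias, empirical standard error, mean square error,
    coverage) with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
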
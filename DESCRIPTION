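Package: dualnback
Title: Simulation, Scoring and Within-Subject Analysis of Dual 2-Back Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dual n-back working-memory experiments run as
    within-subject randomized trials. Generates constrained pseudorandom
    dual 2-back stimulus sequences (targets, lures, fillers), simulates
    synthetic cohorts with configurable signal-detection and reaction-time
    structure, scores trial logs into hit and false-alarm rates, A-prime
    sensitivity, B-double-prime response bias, working-memory capacity,
    reaction-time means and intrasubject variability (whole blocks, half
    blocks, half-block deltas, intermodality discrepancies and
    within-subject ranks), and runs the matching inferential battery:
    one-sample t-tests on deltas, Pearson correlations, Friedman tests on
    ranks, Bonferroni-adjusted pairwise comparisons, repeated-measures
    ANOVA/ANCOVA with Greenhouse-Geisser correction, and random-intercept
    mixed models over both modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
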
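Package: cycleamp
Title: Cardiovascular Amplitude Across the Menstrual Cycle from Wearable Data
Version: 0.1.0
Authors@R:
    person("Morgan", "Hale", email = "morgan.hale@example.org",
           role = c("aut", "cre"))
Description: Quantifies within-cycle fluctuation of wearable-derived resting
    heart rate (RHR) and heart-rate variability (RMSSD) across the menstrual
    cycle. Delineates cycles from daily self-reported bleeding flags, applies
    cohort eligibility filters (cycle length, bleeding length, wear
    percentage), normalizes each metric to its outlier-free within-cycle mean,
    fits a population generalized additive mixed model of the daily offset
    against cycle day with participant random intercepts, and computes a
    peak-to-nadir "cardiovascular amplitude" statistic per cycle and per
    participant. Includes covariate models of amplitude on age, baseline
    metric and BMI, cohort comparisons with 1:1 age matching, and a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    mgcv,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
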
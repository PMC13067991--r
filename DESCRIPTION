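Package: forwardsl
Title: Training-Window Selection for One-Step-Ahead Prediction in
    Non-Stationary Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for one-step-ahead prediction of intensive longitudinal
    outcomes (e.g. ecological momentary assessment of affect) from
    high-frequency covariates when the outcome-covariate relationship drifts
    over time. Provides a time-varying linear data simulator with
    sine-varying coefficients, a library of candidate models differing in
    training window (fraction-of-series grids, last-day heuristics,
    expanding window), three multi-window combiners (simple average,
    discrete super learner, ensemble super learner with simplex-constrained
    weights), and a nested forward-validation engine that constructs the
    combiners on inner rolling-origin folds and evaluates every method
    honestly on held-out next points. Also includes the feature-alignment
    pipeline for passive-sensing data: trailing-window aggregation of sensor
    event streams to questionnaire timestamps under detection, time-shifted
    and lagged conventions, affect-composite construction, near-zero
    variance filtering and leakage-free median imputation, plus a synthetic
    fixture generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
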
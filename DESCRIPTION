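Package: rlbold
Title: Simulating and Recovering Prediction-Error Signals in Reward Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and model-based analysis of probabilistic
    reward-learning experiments of the kind used to study adult age
    differences in frontostriatal prediction-error coding. Generates trial
    schedules for monetary incentive learning (MIL), monetary incentive
    delay (MID) and an expanded four-cue learning task; simulates
    Rescorla-Wagner/softmax, win-stay/lose-shift and random agents; fits the
    delta-rule learning model by maximum likelihood to recover trial-wise
    signed prediction errors; synthesizes ROI BOLD time series whose event
    responses are modulated by prediction error, with drift and AR(1) noise
    in percent-signal-change units; and inverts them with first-level GLMs,
    trial-locked time-course averaging, second-level age regressions, and a
    mixed-design ANOVA on learning performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
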
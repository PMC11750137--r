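Package: probswitch
Title: Behavioral and Photometry Analysis of the Two-Port Probabilistic
    Switching Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of the mouse two-port probabilistic
    switching (reversal) task. Provides a task simulator with pluggable
    choice agents, trial-history behavioral statistics (block-transition
    curves, exponential recovery time constants, history-conditioned
    switch probabilities, training criteria), a recursively formulated
    logistic regression (RFLR) model of choice with stochastic-gradient
    maximum-likelihood fitting and psychometric curves, lock-in style
    demodulation of frequency-modulated fiber-photometry recordings with
    rolling z-score detrending and peri-event alignment, a time-shifted
    kernel ridge regression (GLM) linking behavioral events to the
    demodulated signal with grouped cross-validation and a
    variable-omission analysis, and a synthetic-data generator with known
    ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
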
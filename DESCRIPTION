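Package: chronotimer
Title: Circadian and Sleep-Homeostatic Modulation of Short-Term Interval Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how circadian phase and time awake shape human
    short-term interval timing (duration estimation and production of seconds-range
    targets) under constant-routine protocols. Provides a deterministic
    pacemaker-accumulator clock model with attentional leakage, a synthetic cohort
    generator (mechanistic or model-based backends) including hourly melatonin
    profiles, dim-light melatonin onset (DLMO) estimation by composite 24 h + 12 h
    cosinor fitting with threshold crossing, trial-to-occasion preprocessing with
    outlier filtering, a from-scratch heteroscedastic random-coefficient linear
    mixed model (random intercept plus task and stimulus slopes, residual variance
    multipliers by task-by-stimulus cell, profiled ML/REML), likelihood-ratio model
    comparison over a ladder of trajectory models, and an end-to-end seeded
    simulation/recovery pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    nlme,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
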
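Package: scotovis
Title: Central Versus Peripheral Perceptual Decisions in Scotopic and Photopic Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-interval forced-choice psychophysics of central versus
    peripheral vision under scotopic and photopic viewing. Builds factorial trial
    schedules, simulates generative observers (perceptual-gap, filling-in and
    logit-additive foveal-trust models of the scotopic foveal scotoma), renders the
    calibrated centre-surround grating stimuli, and runs the full analysis chain:
    fixation-validity filtering, observer exclusion, grouped-condition proportion
    metrics with bias-corrected and accelerated (BCa) bootstrap confidence
    intervals, a logit-additivity test of eccentricity biases, trial-order trend
    regression, and the analytic predictions of the competing perceptual
    hypotheses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    stats,
    jsonlite,
    yaml,
    png,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    ggplot2,
    knitr
Config/testthat/edition: 3
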
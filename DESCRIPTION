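Package: tojshift
Title: Time-Shift Analysis of Tactile Localization During Bimanual Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for tactile temporal-order
    judgment (TOJ) experiments in which two stimuli are delivered during a
    bimanual reach and observers report the first stimulus' location with the
    hand they believe was stimulated first. Provides a synthetic-data
    generator implementing three generative accounts of hand-assignment
    errors (time reconstruction, stimulus switch, space-to-limb
    reconstruction), kinematic preprocessing of reach trajectories
    (spline gap interpolation, zero-phase Butterworth filtering,
    velocity-threshold movement onset and offset detection, trial
    exclusion rules), TOJ scoring and movement-phase binning,
    Gaussian-kernel localization-error curves, and a time-shift statistic
    that aligns incorrect-trial localization samples with correct-trial
    template curves to adjudicate between the generative accounts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
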
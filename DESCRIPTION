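Package: gazestep
Title: Double-Step Gaze-Shift Analysis and Spatial-Updating Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye-head double-step gaze-shift experiments:
    double-pole coordinate geometry, saccade detection on calibrated gaze and
    head traces (velocity/acceleration criteria with main-sequence screening),
    per-trial extraction of retinal and motor-error quantities, and multiple
    linear regression comparison of spatial-updating models (no compensation,
    visual feedforward updating, static motor feedback, dynamic motor
    feedback), with bootstrap confidence limits. Includes a synthetic session
    simulator that generates eye-head gaze trajectories with a
    vestibulo-ocular-reflex phase and second responses under a selectable
    ground-truth updating model, so every analysis stage can be exercised and
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
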
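Package: gdmwear
Title: Goal-Directed Movement Detection and Impairment Markers from
    Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting upper-limb goal-directed movements
    (GDM) from tri-axial wrist accelerometer recordings and deriving
    subject-level impairment markers. Includes a synthetic two-wrist
    activities-of-daily-living simulator with impairment-graded reach
    kinematics, Butterworth band-pass preprocessing with downsampling to
    25 Hz and velocity estimation by integration, sliding-window
    segmentation with a one-third GDM labelling rule, a 28-feature signal
    descriptor set (zero-crossing run statistics, spectral and
    distributional moments, axis correlations), a gradient-boosted window
    classifier with geometric-mean threshold selection, leave-one-subject-out
    evaluation, and elastic-net models for stroke-versus-control
    classification and Fugl-Meyer score regression.
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
    glmnet,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
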
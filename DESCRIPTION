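Package: gaitcnn
Title: Joint-Angle Prediction from a Single Tibia-Mounted IMU with a 1D
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hip and knee sagittal flexion angles during
    level-ground running from a single tibia-mounted inertial sensor
    channel, using a compact one-dimensional convolutional neural network
    trained on treadmill running. Includes a synthetic running-gait
    simulator (periodic two-peak knee and single-peak hip waveforms with
    deterministic sensor coupling, stride jitter and surface-dependent
    accelerometer attenuation), signal preparation (foot-strike
    synchronization, anti-aliased resampling, regressor construction,
    steady-state segmentation, sliding-window framing), the network and
    its training loop implemented in C++, gait-event peak metrics (R2,
    RMSE, NRMSE, STD, NSTD, ROM at stance/swing peaks), and an
    orchestrator for intraparticipant and leave-one-participant-out
    experiments comparing accelerometer and gyroscope regressors with
    paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
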
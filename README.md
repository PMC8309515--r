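# gaitcnn

Predicting hip and knee sagittal flexion angles during level-ground
running from a **single tibia-mounted inertial sensor channel**, with a
compact 1-D convolutional network trained on treadmill running — and
comparing the accelerometer against the gyroscope as that single
channel.

## Who this is for

Biomechanics and wearable-sensor researchers who want a tested,
end-to-end reference pipeline for single-IMU joint-angle regression:
signal synchronization and resampling, sliding-window framing, the
network and its training loop, gait-event peak metrics, and
intraparticipant / leave-one-participant-out experiment orchestration.
Real recordings of this kind are rarely deposited, so the package
includes a synthetic running-gait simulator as a first-class module;
every experiment runs end-to-end on simulated cohorts.

## The method

A window of 60 samples (0.6 s at 100 Hz) of one sensor channel
*x(t − 0.3 … t + 0.3)* is mapped to the joint angle *y(t)* at the
window centre by a convolutional network:

    input (60, 1)
    → Conv1D(50, k=3, valid) → (58, 50)
    → Conv1D(50, k=3)        → (56, 50)
    → MaxPool(2)             → (28, 50)
    → Conv1D(100, k=3)       → (26, 100)
    → Conv1D(100, k=3)       → (24, 100)
    → Flatten                → 2400
    → Dense(100, ReLU) → Dense(1, linear)

trained with Adam (lr 0.001, batch 512, 50 epochs, MSE loss,
Glorot-normal init), one independent model per joint × channel × fold.
The two candidate regressors are the tibial-axis accelerometer
component `ay` and the mounting-invariant gyroscope resultant
`sqrt(gx² + gz²)/100`. Training data are the first steady-state minute
of each of four treadmill speeds (2.0–3.5 m/s); the test set is the
first steady-state minute of level-ground running.

Agreement between actual and predicted traces is summarized by R²
(all points), ROM (max − min of the measured trace), and
RMSE / NRMSE / STD / NSTD computed at gait-event peaks — the knee's
stance-phase "small peak" and the hip's flexion maximum — with the
normalized variants expressed as a percentage of ROM. Channels are
compared across participants with two-tailed paired t-tests.

The network, its backpropagation and the Adam loop are implemented in
the package's own C++ (RcppArmadillo, single precision, im2col + BLAS
gemm); no external deep-learning framework is used.

## Worked example

A smoke-scale study: 4 synthetic runners, 30 s sessions, knee joint,
both channels, both evaluation schemes (sessions shorter than 3 min
scale the buffers and segments proportionally; the batch size is
scaled with the training-set size to keep the optimizer's
steps-per-epoch).

```r
library(gaitcnn)
res <- run_study(study_config(n_participants = 4, master_seed = 101,
                              joints = "knee", session_duration = 30,
                              epochs = 5, batch_size = 128))
glance(res)
#> # A tibble: 4 × 11
#>   scheme joint channel               n mean_r2  sd_r2 mean_rmse mean_nrmse mean_std mean_nstd
#>   <chr>  <chr> <chr>             <int>   <dbl>  <dbl>     <dbl>      <dbl>    <dbl>     <dbl>
#> 1 inter  knee  accel_y               4   0.802 0.156       8.99       9.10     1.09      1.11
#> 2 inter  knee  gyro_resultant_xz     4   0.972 0.0290      5.58       5.80     1.40      1.45
#> 3 intra  knee  accel_y               4   0.860 0.0256      9.60       9.96     1.55      1.61
#> 4 intra  knee  gyro_resultant_xz     4   0.988 0.0118      3.97       4.22     1.02      1.06
#>   mean_rom
#>      <dbl>
#> 1     96.9
#> 2     96.9
#> 3     96.9
#> 4     96.9
```

Reading the table: on this synthetic cohort the gyroscope regressor
predicts the knee angle better than the accelerometer in both schemes
(mean R² 0.988 vs 0.860 intraparticipant), and intraparticipant
predictions beat leave-one-out predictions for each channel — the two
directional findings the pipeline is built to exhibit. `tidy(res)`
returns the per-fold metric rows, `res$comparisons` the paired t-test
tables, and `autoplot(res)` the per-fold R² distributions.

Single pieces are exposed too:

```r
cohort <- make_cohort(1, seed = 2)
ses <- simulate_session(cohort[1, ], "treadmill", 2.5, duration = 60)
synchronize(ses$sensor, ses$kinematics)   # recovered clock offset, s
frames <- prepare_frames(ses$sensor, ses$kinematics,
                         "gyro_resultant_xz", "knee",
                         segmentation_plan(60))
fit <- fit_cnn(frames, cnn_config(epochs = 10))
predict(fit, frames)                      # tibble: center_time, .pred
```

A thin command-line wrapper over these functions lives at
`inst/scripts/gaitcnn-study.R` (`simulate` and `full-study`
subcommands).

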
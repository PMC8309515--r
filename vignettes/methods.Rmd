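---
title: "Predicting running joint angles from a single tibia-mounted IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting running joint angles from a single tibia-mounted IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitcnn)
```

## The problem

Joint kinematics during running are normally measured with multi-camera
motion capture or multi-sensor IMU suits, both confined to controlled
settings. A single inertial sensor strapped to the shank is cheap and
unobtrusive, but it does not measure joint angles — it measures linear
acceleration and angular velocity of one segment. `gaitcnn` implements
a data-driven bridge: a compact one-dimensional convolutional network
is trained to map short windows of a single tibia-sensor channel onto
the hip or knee sagittal flexion angle, using treadmill running as the
training condition and level-ground running as the test condition.
The package's second purpose is methodological: it compares two
candidate regressors from the same sensor — the tibial-axis
accelerometer component and the scaled resultant of two gyroscope
components — under an intraparticipant scheme (train and test on the
same runner) and a leave-one-participant-out scheme.

Because the underlying human recordings are not publicly deposited,
the package ships a synthetic running-gait simulator as a first-class,
tested module. Every experiment in the package runs end-to-end on
simulated cohorts.

## The synthetic gait model

`make_cohort()` draws per-runner profiles; `simulate_session()` turns a
profile, a surface and a speed into a paired recording: a 500 Hz
six-channel IMU trace and a 100 Hz hip/knee angle trace.

**Waveforms.** Strides are laid out on a jittered grid (period 60 /
cadence, with a per-stride coefficient of variation of 1–3 %). Within
each stride, phase runs 0 to 1 and the knee flexion curve is a baseline
plus two Gaussian bumps — a small stance peak (default ≈ 40°) at phase
0.18 and a large swing peak (≈ 105°) at phase 0.72 — reproducing the
characteristic two-peak knee morphology of running. The hip curve is a
raised cosine with a single flexion peak (≈ 42°) per cycle at phase
0.85. This is the simplest waveform family with independently
controllable peak values, which the gait-event metrics need as ground
truth.

**Sensor coupling.** The shank-shape signal is the knee curve itself.
Angular velocity is its time derivative scaled by a per-runner gyro
gain (hundreds of deg/s at running cadence); acceleration is its second
derivative scaled by an accel gain (peaks of a few g), plus a constant
gravity projection on the tibial axis. Two aspects of sensor mounting
vary across runners and matter for the science:

* the gravity projection on accel-y (8.8–9.8 m/s², i.e. mounting tilt
  up to ~25°), and
* the rotation of angular velocity between the gyro x and z axes.

The gyro *resultant* sqrt(gx² + gz²) is invariant to that rotation —
which is exactly why that combination is used as the regressor — while
the accelerometer channel inherits a runner-specific offset. This
asymmetry is one mechanism by which leave-one-out transfer is harder
for the accelerometer.

**Surfaces.** A treadmill deck is compliant and vibrating: the default
treadmill model attenuates the dynamic accelerometer component to 0.85
of its level-ground amplitude and adds 1.0 m/s² of belt-vibration
noise; the gyroscope is untouched (attenuation 1). The physical
motivation is that impact accelerations are absorbed by the belt while
segment rotation is not. Neither quantity is measured anywhere we know
of, so both are free simulation parameters; they were calibrated once
so that the accelerometer penalty is a *perturbation* — synthetic
intraparticipant accelerometer R² stays near 0.9, as in real
treadmill-to-overground studies — rather than a dominating distortion,
and then frozen. All downstream claims are directional, not tied to
these values.

**Hip difficulty.** Real hip-angle recordings from IMU suits suffer
offset drift, and hip predictions from a shank sensor are consistently
worse than knee predictions. The simulator emulates this with a slow
spline-interpolated baseline wander (knots every 5 s, SD 4–7°) plus
per-stride amplitude variability (CV 8–15 %) on the hip curve only.
Neither is visible to a 0.6 s shank-sensor window, so they cap hip
predictability below the knee's regardless of model capacity.

**Synchronization.** Both systems record three foot-strike pulses
(40 ms rectangles) at identical true times early in the trial; the
sensor clock lags the kinematics clock by a uniform 0–0.5 s offset.
Pulse amplitude is five times the marker channel's *peak* deviation:
running accelerometry has a crest factor near five, so RMS-scaled
pulses would be indistinguishable from ordinary impact transients.
For sessions shorter than 3 min the strike times scale with session
length so they stay inside the scaled ingress buffer.

**What the simulator does not model:** ground-reaction forces, soft
tissue artefact, frontal/transverse-plane motion, ankle kinematics,
magnetometer effects, or any musculoskeletal constraint. Passing tests
therefore demonstrate that the *pipeline* behaves as specified on data
with the assumed statistical structure, not that the method attains any
particular accuracy on real runners.

## Signal preparation

* `synchronize()` detects the three strike onsets on each side from the
  largest sample-to-sample jumps of the marker channel (accel-y for the
  sensor, the knee derivative for the kinematics) and returns the mean
  onset difference; on simulated sessions the offset is recovered to
  within one 100 Hz sample.
* `resample_to_target_rate()` low-passes at 40 Hz (4th-order
  Butterworth, forward–backward so zero phase, reflective padding to
  kill edge transients) and decimates 500 Hz → 100 Hz. Gait content
  lives below ~20 Hz, so the passband is untouched.
* `build_regressor()` forms either `accel_y` (unchanged) or
  `gyro_resultant_xz` = sqrt(gx² + gz²)/100; the 1/100 rescale brings
  hundreds of deg/s into the same numerical range as accelerations so
  one fixed training recipe serves both channels.
* `segmentation_plan()` drops a 15 s ingress buffer at each end of a
  3 min session and splits the rest into 60 + 60 + 30 s, keeping the
  first 60 s set. Other session lengths scale every piece
  proportionally — this is how smoke-scale studies shrink.
* `make_frames()` cuts stride-1 overlapping windows of 60 samples
  (0.6 s); the target of frame *i* is the angle at its centre sample
  *i* + 30, and a length-*L* segment yields *L* − 59 frames. Frames are
  built per segment before pooling, so no window ever spans a
  concatenation splice; pooled manifests record source order
  (ascending participant, then ascending speed).

## The network

`cnn_config()` fixes the architecture: four valid-padding Conv1D
layers (50, 50, 100, 100 filters, kernel 3, stride 1), 2:1 max pooling
after the second, a 100-unit dense ReLU layer and a linear scalar
output. On a 60-sample window the feature lengths run
58 → 56 → 28 → 26 → 24, flattening to 2400. Training is Adam
(learning rate 0.001), mean squared error, Glorot-normal
initialisation, 50 epochs at batch size 512, no validation split and
no early stopping; one independent model is trained per joint ×
channel × fold. Since no deep-learning framework is available in this
R stack, the forward pass, backpropagation and the Adam loop are
implemented in the package's own C++ (RcppArmadillo, single
precision, convolutions lowered to BLAS gemm via im2col).
`fit_cnn()` is bit-reproducible given its seed; predictions are
reproducible across batch compositions to single-precision rounding.

**Scaling down.** Smoke studies shorten sessions (30–60 s) and epochs
(5–12) through `study_config`. One subtlety: batch size must scale with
the training-set size. The full protocol yields ~24 000 frames, i.e.
47 optimizer steps per epoch at batch 512; a 30 s-session study yields
3 764 frames, which at batch 512 is only 8 steps per epoch — every
model is then grossly under-converged and comparisons measure optimizer
noise, not the science. Smoke runs therefore use batch 128
(≈ 512 × 3764/23941), restoring the steps-per-epoch of the full
recipe. Full-scale defaults are untouched.

## Evaluation

Six statistics compare an actual and a predicted level-ground trace
(`angle_metrics()`):

* **R²** over all points, 1 − SS~res~/SS~tot~;
* **ROM**, max − min of the measured trace (the measured trace only,
  so normalization never depends on model output);
* **RMSE** and **STD** over residuals at matched gait-event peaks —
  the knee's stance-phase "small peak" and the hip's flexion maximum;
* **NRMSE** and **NSTD**, the former two as a percentage of ROM.

Peak detection (`detect_peaks()`) delimits cycles by the swing maxima
(the per-cycle global maxima, thinned to at least 0.35 s apart) and
takes the stance event as the highest interior local maximum below the
swing band; the same algorithm is applied to actual and predicted
traces. Matching (`match_peaks()`) is greedy nearest-in-time within
±0.25 s — under half a stride, so events cannot jump cycles. STD uses
the sample standard deviation (n − 1 denominator), appropriate for the
small per-trace event counts. NSTD mirrors NRMSE (peak residual SD
over ROM); the alternative all-points reading of its definition is
noted as an open interpretation, and the peak-based one is
implemented. Folds whose predicted trace yields no matched peaks carry
`NA` peak metrics and are dropped pairwise from that parameter's
group test, with the pair count reported.

`paired_comparison()` runs two-tailed paired t-tests (accelerometer
minus gyroscope, so negative t favours the gyro on R² and positive t
favours it on error metrics), significance at p < 0.05, and labels
mean R² values by the conventional correlation-strength bins
(0–0.10 negligible, 0.10–0.39 weak, 0.40–0.69 moderate, 0.70–0.89
strong, 0.90–1.00 very strong).

## The study runner

`run_study()` orchestrates everything: simulate the cohort (four
treadmill speeds 2.0–3.5 m/s plus one level-ground session at a
preferred speed drawn from N(2.44, 0.34) m/s truncated to (1.5, 3.5)),
prepare frames once per session × channel, then train and evaluate one
network per scheme × joint × channel × fold. The intra scheme trains
on a runner's own four concatenated treadmill segments (4 min of data
at full scale) and tests on their level-ground segment; the inter
scheme runs a leave-one-out fold per participant, pooling the other
runners' treadmill frames in ascending participant order. A single
master seed fans out to every cohort draw, session and fold seed
through a splitter (`child_seed()`), so one integer reproduces a whole
study.

```{r study, eval = FALSE}
library(gaitcnn)
res <- run_study(study_config(n_participants = 4, master_seed = 101,
                              joints = "knee", session_duration = 30,
                              epochs = 5, batch_size = 128))
glance(res)        # mean (SD) metrics per scheme x joint x channel
res$comparisons    # paired accelerometer-vs-gyroscope tables
autoplot(res)      # per-fold R2 distributions
```

On synthetic cohorts at this smoke scale the package reproduces the
three qualitative findings it is built around, and the test suite
asserts them: the gyroscope regressor outperforms the accelerometer
(because the treadmill perturbs the accelerometer's training
amplitude and noise while the mounting-invariant gyro resultant
transfers cleanly), intraparticipant predictions beat leave-one-out
predictions, and knee angles are predicted better than hip angles.

## Numerical choices and degenerate inputs

* Clock alignment interpolates the resampled regressor onto the
  kinematics grid over the common time span; the few samples trimmed at
  the edges are absorbed by a 0.5 s slack in the segment-duration
  check.
* R² is undefined for a constant measured trace and NRMSE/NSTD for
  zero ROM; both raise a typed metric error rather than returning
  infinities. Monotone inputs yield zero knee stance events without
  error. Sessions shorter than 30 s, flat (spikeless) marker channels
  and mismatched grids raise typed argument/synchronization errors.
* Training aborts with the epoch number if the loss turns non-finite;
  partial final batches are trained on, not dropped.
* The problem sizes used by the shipped tests and the acceptance
  script — cohorts of 1–4 runners, 30–60 s sessions, 5–12 epochs —
  were chosen as the smallest sizes at which training converges enough
  for the directional comparisons to measure signal rather than
  optimizer noise.

## Known limitations

The simulator's coupling between sensor and angles is far cleaner than
reality (no soft-tissue artefact, no cross-axis leakage beyond the
fixed mixes, no fatigue drift in the knee), so absolute synthetic R²
values are optimistic and are never compared against real-study
numbers. The treadmill attenuation and belt-noise magnitudes are
assumptions, not estimates. Only sagittal hip and knee angles are
modelled; ankle kinematics are out of scope. Bit-exact reproducibility
of training holds for a fixed BLAS; across different BLAS builds
agreement is statistical, not bitwise.
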
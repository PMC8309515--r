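test_that("cohorts are deterministic and respect physiological orderings", {
  co <- make_cohort(10, seed = 1)
  expect_equal(nrow(co), 10)
  expect_identical(co, make_cohort(10, seed = 1))
  expect_true(all(co$knee_stance_peak < co$knee_swing_peak))
  expect_true(all(co$knee_min < co$knee_stance_peak))
  expect_true(all(co$hip_min < co$hip_peak))
  expect_true(all(co$noise_sd_accel >= 0 & co$noise_sd_gyro >= 0))
  expect_true(all(co$stride_jitter_cv >= 0 & co$stride_jitter_cv <= 0.2))
  # profiles differ across participants
  expect_gt(length(unique(co$cadence_base)), 1)

  co2 <- make_cohort(2, seed = 7)
  expect_true(all(co2$knee_stance_peak < co2$knee_swing_peak))
  expect_error(make_cohort(0), class = "gaitcnn_argument_error")
})

test_that("sessions have the right shapes, metadata and determinism", {
  prof <- quiet_profile()
  ses <- simulate_session(prof, "level_ground", 2.5, duration = 30)
  expect_s3_class(ses$sensor, "sensor_recording")
  expect_s3_class(ses$kinematics, "kinematics_recording")
  expect_equal(nrow(ses$sensor), 30 * 500)
  expect_equal(nrow(ses$kinematics), 30 * 100)
  m <- recording_meta(ses$sensor)
  expect_length(m$sync_events, 3)
  expect_true(all(m$sync_events < 10))
  expect_true(all(diff(ses$sensor$t) > 0))
  # sensor clock lags the kinematics clock by at most 0.5 s
  lag <- m$sync_events - recording_meta(ses$kinematics)$sync_events
  expect_true(all(lag >= 0 & lag <= 0.5))

  ses2 <- simulate_session(prof, "level_ground", 2.5, duration = 30)
  expect_identical(ses$sensor, ses2$sensor)
  expect_identical(ses$kinematics, ses2$kinematics)

  expect_error(simulate_session(prof, "treadmill", 2.5, duration = 20),
               class = "gaitcnn_argument_error")
  expect_error(simulate_session(prof, "treadmill", -1, duration = 60),
               class = "gaitcnn_argument_error")
})

test_that("noise-free knee cycles carry two maxima (stance below swing), hip one", {
  prof <- quiet_profile(stride_jitter_cv = 0, hip_amp_cv = 0,
                        hip_drift_sd = 0)
  ses <- simulate_session(prof, quiet_surface("level_ground"), 2.5,
                          duration = 40)
  kin <- ses$kinematics
  period <- 60 / prof$cadence_base
  # analyse whole cycles after the sync pulses have passed
  t0 <- ceiling(6 / period) * period
  n_cyc <- floor((max(kin$t) - 1 - t0) / period)
  thr <- min(kin$knee) + 0.5 * (max(kin$knee) - min(kin$knee))
  for (k in seq_len(n_cyc) - 1) {
    inside <- kin$t >= t0 + k * period & kin$t < t0 + (k + 1) * period
    knee <- kin$knee[inside]
    hip <- kin$hip[inside]
    km <- gaitcnn:::local_maxima(knee)
    expect_length(km, 2)
    # smaller (stance) peak precedes the larger (swing) peak
    expect_lt(knee[km[1]], knee[km[2]])
    expect_lt(knee[km[1]], thr)
    expect_length(gaitcnn:::local_maxima(hip), 1)
  }
})

test_that("treadmill attenuation scales accelerometer but not gyroscope", {
  prof <- quiet_profile()
  tread <- quiet_surface("treadmill", accel_attenuation = 0.7)
  level <- quiet_surface("level_ground")
  seed <- 99
  st <- simulate_session(prof, tread, 2.5, 40, seed = seed)
  sl <- simulate_session(prof, level, 2.5, 40, seed = seed)
  # compare away from the sync pulses
  keep <- st$sensor$t - st$sensor$t[1] > 10
  dyn_rms <- function(x) sqrt(mean((x - mean(x))^2))
  ratio <- dyn_rms(st$sensor$ay[keep]) / dyn_rms(sl$sensor$ay[keep])
  expect_equal(ratio, 0.7, tolerance = 0.01)
  expect_lt(dyn_rms(st$sensor$ax[keep]) / dyn_rms(sl$sensor$ax[keep]), 1)
  # gyro channels identical when gyro_attenuation is 1 on both surfaces
  expect_equal(st$sensor$gx, sl$sensor$gx, tolerance = 1e-12)
  rms_ratio <- dyn_rms(st$sensor$gz[keep]) / dyn_rms(sl$sensor$gz[keep])
  expect_lt(abs(rms_ratio - 1), 0.01)
})

test_that("gyro resultant shares the knee trace's fundamental period", {
  prof <- quiet_profile(stride_jitter_cv = 0)
  ses <- simulate_session(prof, quiet_surface("level_ground"), 2.5, 40)
  low <- resample_to_target_rate(ses$sensor)
  reg <- build_regressor(low, "gyro_resultant_xz")
  keep_r <- reg$t - reg$t[1] > 10
  keep_k <- ses$kinematics$t > 10
  lag_of <- function(x) {
    a <- stats::acf(x, lag.max = 150, plot = FALSE)$acf[-1]
    peaks <- gaitcnn:::local_maxima(a)
    peaks[which.max(a[peaks])]
  }
  expect_lte(abs(lag_of(reg$x[keep_r]) - lag_of(ses$kinematics$knee[keep_k])),
             1)
})

test_that("a study simulates 5 sessions per participant with the stated speeds", {
  co <- make_cohort(10, seed = 5)
  study <- simulate_study(co, seed = 5, session_duration = 30)
  expect_equal(nrow(study), 50)
  expect_equal(sum(study$surface == "treadmill"), 40)
  per <- dplyr::count(study, participant_id)
  expect_true(all(per$n == 5))
  tread_speeds <- sort(unique(study$speed[study$surface == "treadmill"]))
  expect_equal(tread_speeds, c(2.0, 2.5, 3.0, 3.5))
  pref <- study$speed[study$surface == "level_ground"]
  expect_true(all(pref > 1.5 & pref < 3.5))
  expect_true(all(study$duration == 30))
})

test_that("preferred-speed sampler is calibrated to 2.44 m/s", {
  sp <- sample_preferred_speeds(1000, seed = 4)
  expect_lt(abs(mean(sp) - 2.44), 0.05)
  expect_true(all(sp > 1.5 & sp < 3.5))
})

test_that("sessions survive a CSV + JSON round trip", {
  prof <- quiet_profile()
  ses <- simulate_session(prof, "treadmill", 3.0, 30)
  stem <- file.path(withr::local_tempdir(), "p1_treadmill")
  write_session(ses, stem)
  back <- read_session(stem)
  expect_equal(back$sensor$ay, ses$sensor$ay, tolerance = 1e-12)
  expect_equal(back$kinematics$knee, ses$kinematics$knee, tolerance = 1e-12)
  expect_equal(recording_meta(back$sensor), recording_meta(ses$sensor),
               tolerance = 1e-12)
})
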
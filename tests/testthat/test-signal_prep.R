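test_that("clock offsets are recovered from the sync pulses", {
  prof <- make_cohort(3, seed = 8)
  for (i in 1:3) {
    ses <- simulate_session(prof[i, ], "level_ground", 2.0 + i * 0.5, 30)
    true_off <- recording_meta(ses$sensor)$sync_events[1] -
      recording_meta(ses$kinematics)$sync_events[1]
    est <- synchronize(ses$sensor, ses$kinematics)
    expect_lt(abs(est - true_off), 0.01)
  }
})

test_that("self-alignment gives a zero offset and flat signals fail", {
  ses <- simulate_session(quiet_profile(), "treadmill", 2.5, 30)
  expect_equal(synchronize(ses$sensor, ses$sensor), 0)
  flat <- sensor_recording(
    t = seq(0, 14.998, by = 0.002), ax = rep(0, 7500), ay = rep(0, 7500),
    az = rep(0, 7500), gx = rep(0, 7500), gy = rep(0, 7500),
    gz = rep(0, 7500), participant_id = "X", surface = "treadmill",
    speed = 2, sample_rate = 500
  )
  err <- expect_error(synchronize(flat, ses$kinematics),
                      class = "gaitcnn_sync_error")
  expect_match(conditionMessage(err), "sensor")
  err2 <- expect_error(
    synchronize(ses$sensor, kin_from_vectors(rep(1, 1500))),
    class = "gaitcnn_sync_error"
  )
  expect_match(conditionMessage(err2), "kinematics")
})

test_that("resampling decimates 5:1 and passes gait-band content untouched", {
  t <- seq(0, 180 - 0.002, by = 0.002)
  sine <- sin(2 * pi * 2 * t)
  sens <- sensor_recording(t, sine, sine, sine, sine, sine, sine,
                           participant_id = "X", surface = "treadmill",
                           speed = 2, sample_rate = 500)
  low <- resample_to_target_rate(sens)
  expect_equal(nrow(low), 18000)
  expect_equal(recording_meta(low)$sample_rate, 100)
  expect_lt(max(abs(low$ay - sin(2 * pi * 2 * low$t))), 1e-3)

  bad <- sens
  attr(bad, "sample_rate") <- 300
  expect_error(resample_to_target_rate(bad),
               class = "gaitcnn_argument_error")
})

test_that("regressor channels follow their definitions", {
  n <- 100
  t <- seq(0, by = 0.01, length.out = n)
  sens <- sensor_recording(t, ax = rep(1, n), ay = 1:n, az = rep(2, n),
                           gx = rep(3, n), gy = rep(9, n), gz = rep(4, n),
                           participant_id = "X", surface = "treadmill",
                           speed = 2, sample_rate = 100)
  acc <- build_regressor(sens, "accel_y")
  expect_equal(acc$x, as.numeric(1:n))
  gyr <- build_regressor(sens, "gyro_resultant_xz")
  # 3-4-5 triangle scaled down by 100
  expect_equal(gyr$x, rep(0.05, n))
  zero <- sensor_recording(t, ax = rep(0, n), ay = rep(0, n), az = rep(0, n),
                           gx = rep(0, n), gy = rep(0, n), gz = rep(0, n),
                           participant_id = "X", surface = "treadmill",
                           speed = 2, sample_rate = 100)
  expect_equal(build_regressor(zero, "gyro_resultant_xz")$x, rep(0, n))
  expect_error(build_regressor(sens, "accel_x"))
})

test_that("segmentation keeps the first steady-state minute", {
  plan <- segmentation_plan(180)
  expect_equal(plan$buffer_head + plan$buffer_tail + sum(plan$split), 180)
  kin <- kin_from_vectors(rnorm(18000))
  seg <- segment_session(kin, plan)
  expect_equal(nrow(seg), 6000)
  expect_true(min(seg$t) >= 15 && max(seg$t) < 75)

  short <- kin_from_vectors(rnorm(17000))
  err <- expect_error(segment_session(short, plan),
                      class = "gaitcnn_argument_error")
  expect_match(conditionMessage(err), "170")
  expect_error(segmentation_plan(180, buffer_head = 20),
               class = "gaitcnn_argument_error")
})

test_that("framing yields L - 59 centred windows", {
  mk <- function(L) {
    x <- reg_from_vector(seq_len(L) / 10)
    k <- kin_from_vectors(100 + seq_len(L))
    make_frames(x, k, "knee")
  }
  f1 <- mk(60)
  expect_equal(n_frames(f1), 1)
  expect_equal(f1$y, 100 + 31)           # target is the centre sample
  expect_equal(f1$X[1, ], seq_len(60) / 10)

  expect_equal(n_frames(mk(120)), 61)
  expect_equal(n_frames(mk(24000)), 23941)
  expect_error(mk(59), class = "gaitcnn_argument_error")

  x <- reg_from_vector(rnorm(100))
  k <- kin_from_vectors(rnorm(99))
  expect_error(make_frames(x, k, "knee"),
               class = "gaitcnn_argument_error")
})

test_that("the window centre is the most informative sample for an identity target", {
  withr::local_seed(3)
  raw <- stats::filter(rnorm(1200), rep(1 / 15, 15), sides = 2)
  raw[is.na(raw)] <- 0
  x <- reg_from_vector(as.numeric(raw))
  k <- kin_from_vectors(as.numeric(raw))
  fr <- make_frames(x, k, "knee")
  cors <- apply(fr$X, 2, stats::cor, y = fr$y)
  expect_equal(which.max(cors), 31)
})

test_that("pooled frame sets preserve source order and refuse mixtures", {
  x <- reg_from_vector(rnorm(100))
  k <- kin_from_vectors(rnorm(100))
  f1 <- make_frames(x, k, "knee")
  f2 <- f1
  f2$manifest$speed <- 3.0
  pooled <- bind_frame_sets(list(f1, f2))
  expect_equal(n_frames(pooled), 2 * n_frames(f1))
  expect_equal(pooled$manifest$speed, c(2.5, 3.0))
  f3 <- make_frames(x, k, "hip")
  expect_error(bind_frame_sets(list(f1, f3)),
               class = "gaitcnn_argument_error")
})

test_that("prepare_frames chains the full preprocessing deterministically", {
  ses <- simulate_session(quiet_profile(), "treadmill", 2.5, 30)
  plan <- segmentation_plan(30)
  fr <- prepare_frames(ses$sensor, ses$kinematics, "gyro_resultant_xz",
                       "knee", plan)
  # 10 s selected segment at 100 Hz
  expect_equal(n_frames(fr), 1000 - 59)
  fr2 <- prepare_frames(ses$sensor, ses$kinematics, "gyro_resultant_xz",
                        "knee", plan)
  expect_identical(fr$X, fr2$X)
  expect_identical(fr$y, fr2$y)
})
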
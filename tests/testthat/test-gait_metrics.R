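test_that("metric formulas match brute-force recomputation on random traces", {
  withr::local_seed(20)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    y <- rnorm(n, 50, 20)
    yhat <- y + rnorm(n, 0, 5)
    expect_equal(r_squared(y, yhat), brute_r2(y, yhat), tolerance = 1e-10)
    expect_equal(rom(y), max(y) - min(y), tolerance = 1e-10)
    pairs <- tibble::tibble(value_actual = y, value_pred = yhat)
    pk <- peak_rmse_std(pairs)
    expect_equal(pk$rmse, brute_rmse(y - yhat), tolerance = 1e-10)
    expect_equal(pk$std, brute_sd(y - yhat), tolerance = 1e-10)
  }
})

test_that("R2 identity, null model and hand-computed cases are exact", {
  y <- c(4, 7, 9, 3)
  expect_identical(r_squared(y, y), 1)
  expect_identical(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(rep(2, 5), rnorm(5)), class = "gaitcnn_metric_error")
  expect_error(r_squared(1:3, 1:2), class = "gaitcnn_argument_error")
})

test_that("ROM, peak residual statistics and normalization follow their definitions", {
  expect_equal(rom(c(20, 140, 60)), 120)
  expect_equal(rom(rep(5, 10)), 0)
  expect_error(normalized(1, rom(rep(5, 10))), class = "gaitcnn_metric_error")

  pr <- function(r) tibble::tibble(value_actual = r, value_pred = 0)
  expect_equal(peak_rmse_std(pr(c(1, 1))), list(rmse = 1, std = 0))
  pk <- peak_rmse_std(pr(c(0, 2)))
  expect_equal(pk$rmse, sqrt(2))
  expect_equal(pk$std, sqrt(2))
  expect_equal(peak_rmse_std(pr(c(-3, 3)))$rmse, 3)
  expect_error(peak_rmse_std(pr(numeric(0))), class = "gaitcnn_metric_error")

  expect_equal(normalized(5, 50), 10)
  expect_equal(normalized(0, 50), 0)
  expect_equal(normalized(4.4, 88.7), 4.96054, tolerance = 1e-5)
})

test_that("knee stance and hip peaks are detected on constructed waveforms", {
  period <- 0.75
  t <- seq(0, 12, by = 0.01)
  phi <- (t %% period) / period
  knee <- gaitcnn:::knee_curve(phi, 10, 25, 70)
  det <- detect_peaks(tibble::tibble(t = t, value = knee), "knee")
  expect_gt(nrow(det), 10)
  expect_true(all(abs(det$value - 25) < 0.1))
  # one stance event per interior cycle, at the stance phase
  expect_true(all(abs((det$time %% period) / period - 0.18) < 0.02))

  hip <- 15 + 25 * sin(2 * pi * t / period)
  hdet <- detect_peaks(tibble::tibble(t = t, value = hip), "hip")
  expect_true(all(abs(hdet$value - 40) < 0.05))
  expect_equal(nrow(hdet), 16)

  ramp <- detect_peaks(tibble::tibble(t = t, value = t), "knee")
  expect_equal(nrow(ramp), 0)
  expect_error(detect_peaks(tibble::tibble(t = c(0, 1), value = c(0, 1)),
                            "hip"),
               class = "gaitcnn_argument_error")
})

test_that("peak matching is greedy, tolerance-bounded and one-to-one", {
  pk <- function(times) tibble::tibble(time = times,
                                       value = seq_along(times),
                                       kind = "knee_stance_peak")
  a <- pk(c(1, 2, 3, 4))
  m0 <- match_peaks(a, a)
  expect_equal(nrow(m0), 4)
  expect_equal(m0$value_actual, m0$value_pred)
  expect_equal(attr(m0, "n_unmatched_actual"), 0)

  m1 <- match_peaks(a, pk(c(1, 2, 3, 4) + 0.1))
  expect_equal(nrow(m1), 4)
  expect_equal(m1$time_pred - m1$time_actual, rep(0.1, 4))

  m2 <- match_peaks(a, pk(c(1, 2, 3, 4) + 0.4))
  expect_equal(nrow(m2), 0)
  expect_equal(attr(m2, "n_unmatched_pred"), 4)
})

test_that("scaling both traces leaves the normalized metrics invariant", {
  withr::local_seed(21)
  k <- -2.5
  y <- 40 + 25 * sin(seq(0, 20, 0.01)) + rnorm(2001)
  yhat <- y + rnorm(2001, 0, 2)
  expect_equal(r_squared(k * y, k * yhat), r_squared(y, yhat))
  expect_equal(rom(k * y), abs(k) * rom(y))
  pairs <- tibble::tibble(value_actual = y[1:20], value_pred = yhat[1:20])
  pairs_k <- tibble::tibble(value_actual = k * y[1:20],
                            value_pred = k * yhat[1:20])
  expect_equal(peak_rmse_std(pairs_k)$rmse,
               abs(k) * peak_rmse_std(pairs)$rmse)
  expect_equal(normalized(peak_rmse_std(pairs_k)$rmse, rom(k * y)),
               normalized(peak_rmse_std(pairs)$rmse, rom(y)))
})

test_that("emitted metric reports satisfy the NRMSE/NSTD identities", {
  prof <- quiet_profile(stride_jitter_cv = 0.01)
  ses <- simulate_session(prof, quiet_surface("level_ground"), 2.5, 30)
  kin <- ses$kinematics
  keep <- kin$t >= 5 & kin$t < 25
  seg <- kin[keep, ]
  withr::local_seed(22)
  pred <- tibble::tibble(center_time = seg$t,
                         .pred = seg$knee + rnorm(sum(keep), 0, 1.5))
  m <- angle_metrics(seg, pred, "knee")
  expect_equal(m$nrmse, 100 * m$rmse / m$rom, tolerance = 1e-12)
  expect_equal(m$nstd, 100 * m$std / m$rom, tolerance = 1e-12)
  expect_lte(m$r2, 1)
  expect_gt(m$n_peaks_matched, 10)
})

test_that("correlation strength labels follow the published bins", {
  expect_equal(schober_label(c(0.05, 0.2, 0.5, 0.85, 0.95)),
               c("negligible", "weak", "moderate", "strong", "very strong"))
  expect_equal(schober_label(0.90), "very strong")
  expect_equal(schober_label(0.10), "weak")
})

test_that("the paired t-test matches its closed form and flags degeneracy", {
  cmp <- paired_comparison(c(0.93, 0.85), c(0.96, 0.90), parameter = "r2")
  expect_equal(cmp$t_statistic, -4, tolerance = 1e-9)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$p_value, 2 * stats::pt(-4, df = 1), tolerance = 1e-9)
  expect_false(cmp$significant)
  expect_equal(cmp$schober_accel, "strong")
  expect_equal(cmp$schober_gyro, "very strong")

  expect_error(paired_comparison(c(1, 2), c(1, 2)),
               class = "gaitcnn_metric_error")
  expect_error(paired_comparison(1, 1), class = "gaitcnn_argument_error")
})
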
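# Gait-event peak detection and the six evaluation statistics
# (R2, RMSE, NRMSE, STD, NSTD, ROM), plus the paired accelerometer vs
# gyroscope comparison.

#' Detect per-cycle gait-event peaks in an angle trace
#'
#' For the hip the event is the per-cycle flexion maximum. For the knee
#' it is the stance-phase "small peak": cycles are delimited by the
#' swing maxima (the per-cycle global maxima), and the event is the
#' highest local maximum strictly between consecutive swing peaks that
#' stays below the swing band; cycles without an interior maximum yield
#' no event.
#'
#' @param trace A data frame with a `t` column (seconds, 100 Hz grid)
#'   and the angle in a column named after the joint (or `value`).
#' @param joint `"knee"` or `"hip"`.
#' @param min_period Minimum separation between cycle-defining maxima,
#'   seconds (default 0.35, half a typical stride).
#' @return A tibble with `time`, `value` and `kind`
#'   (`knee_stance_peak` or `hip_peak_flexion`).
#' @export
detect_peaks <- function(trace, joint = c("knee", "hip"),
                         min_period = 0.35) {
  joint <- match.arg(joint)
  t <- trace$t
  x <- trace[[joint]] %||% trace[["value"]]
  if (is.null(x)) stop_arg("trace needs a '%s' or 'value' column", joint)
  if (length(t) < 2 || (max(t) - min(t)) < 2) {
    stop_arg("trace must span at least 2 s")
  }
  lm_idx <- local_maxima(x)
  kind <- if (joint == "knee") "knee_stance_peak" else "hip_peak_flexion"
  empty <- tibble(time = numeric(0), value = numeric(0),
                  kind = character(0))
  if (length(lm_idx) == 0) return(empty)

  thr_frac <- if (joint == "knee") 0.6 else 0.5
  thr <- min(x) + thr_frac * (max(x) - min(x))
  major <- major_peaks(t, x, lm_idx, thr, min_period)
  if (joint == "hip") {
    if (length(major) == 0) return(empty)
    return(tibble(time = t[major], value = x[major], kind = kind))
  }
  if (length(major) < 2) return(empty)
  stance <- integer(0)
  for (j in seq_len(length(major) - 1L)) {
    interior <- lm_idx[lm_idx > major[j] & lm_idx < major[j + 1L] &
                         x[lm_idx] < thr]
    if (length(interior)) stance <- c(stance, interior[which.max(x[interior])])
  }
  if (length(stance) == 0) return(empty)
  tibble(time = t[stance], value = x[stance], kind = kind)
}

# Cycle-defining maxima: local maxima above `thr`, thinned greedily by
# descending height so that no two survive within `min_period`.
major_peaks <- function(t, x, lm_idx, thr, min_period) {
  cand <- lm_idx[x[lm_idx] >= thr]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[kept]) >= min_period)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Pair detected peaks of an actual and a predicted trace
#'
#' Greedy nearest-in-time matching: candidate pairs within the time
#' tolerance are taken in order of increasing time difference, each
#' event used at most once. Unmatched counts are kept as attributes.
#'
#' @param actual,predicted Peak tibbles from [detect_peaks()].
#' @param tol Matching tolerance in seconds (default 0.25, under half a
#'   stride so events cannot jump cycles).
#' @return A tibble with `time_actual`, `value_actual`, `time_pred`,
#'   `value_pred`; attributes `n_unmatched_actual` and
#'   `n_unmatched_pred`.
#' @export
match_peaks <- function(actual, predicted, tol = 0.25) {
  na <- nrow(actual)
  np <- nrow(predicted)
  pairs <- tidyr::expand_grid(i = seq_len(na), j = seq_len(np))
  if (nrow(pairs) > 0) {
    pairs$dt <- abs(actual$time[pairs$i] - predicted$time[pairs$j])
    pairs <- pairs[pairs$dt <= tol, ]
    pairs <- pairs[order(pairs$dt), ]
  }
  used_i <- logical(na)
  used_j <- logical(np)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_i[i] && !used_j[j]) {
      keep[r] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  pairs <- pairs[keep, ]
  pairs <- pairs[order(pairs$i), ]
  out <- tibble(
    time_actual = actual$time[pairs$i],
    value_actual = actual$value[pairs$i],
    time_pred = predicted$time[pairs$j],
    value_pred = predicted$value[pairs$j]
  )
  attr(out, "n_unmatched_actual") <- sum(!used_i)
  attr(out, "n_unmatched_pred") <- sum(!used_j)
  out
}

#' Coefficient of determination over all points
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param actual,predicted Equal-length numeric vectors (>= 2 points).
#' @return A single number (<= 1).
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2) {
    stop_arg("actual and predicted must have equal length >= 2")
  }
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop_metric("R2 undefined for a constant actual trace")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Range of motion of a trace
#'
#' @param x Numeric vector of angles (degrees).
#' @return `max(x) - min(x)` in degrees.
#' @export
rom <- function(x) {
  if (length(x) == 0) stop_arg("trace is empty")
  max(x) - min(x)
}

#' RMSE and residual standard deviation at matched peak events
#'
#' @param pairs A tibble from [match_peaks()] (columns `value_actual`,
#'   `value_pred`).
#' @return A list with `rmse` (degrees) and `std` (sample standard
#'   deviation of the residuals, degrees; `NA` for a single pair).
#' @export
peak_rmse_std <- function(pairs) {
  if (nrow(pairs) == 0) stop_metric("no matched peak pairs")
  resid <- pairs$value_actual - pairs$value_pred
  list(rmse = sqrt(mean(resid^2)),
       std = if (length(resid) >= 2) sd(resid) else NA_real_)
}

#' Normalize an error metric by the range of motion
#'
#' @param metric Error in degrees.
#' @param rom Range of motion in degrees (> 0), from the measured
#'   trace.
#' @return The metric as a percentage of ROM.
#' @export
normalized <- function(metric, rom) {
  if (!is.finite(rom) || rom <= 0) {
    stop_metric("normalization undefined for ROM <= 0")
  }
  100 * metric / rom
}

#' All six evaluation statistics for one actual/predicted trace pair
#'
#' R2 is computed over all points; RMSE and STD over residuals at the
#' matched gait-event peaks (knee stance peak or hip peak flexion);
#' NRMSE and NSTD divide those by the measured trace's range of motion,
#' in percent.
#'
#' @param actual A kinematics segment (tibble with `t` and the joint
#'   column).
#' @param predicted A prediction tibble with `center_time` and `.pred`
#'   on the same grid.
#' @param joint `"knee"` or `"hip"`.
#' @return A one-row tibble: `joint`, `r2`, `rom`, `rmse`, `nrmse`,
#'   `std`, `nstd`, `n_peaks_matched`, `n_peaks_unmatched`.
#' @export
angle_metrics <- function(actual, predicted, joint = c("knee", "hip")) {
  joint <- match.arg(joint)
  idx <- match(round(predicted$center_time * 1000),
               round(actual$t * 1000))
  if (anyNA(idx)) {
    stop_data("predicted centre times do not all lie on the actual grid")
  }
  y <- actual[[joint]][idx]
  yhat <- predicted$.pred
  r2 <- r_squared(y, yhat)
  range_y <- rom(y)
  actual_trace <- tibble(t = predicted$center_time, value = y)
  pred_trace <- tibble(t = predicted$center_time, value = yhat)
  pk_a <- detect_peaks(actual_trace, joint)
  pk_p <- detect_peaks(pred_trace, joint)
  pairs <- match_peaks(pk_a, pk_p)
  pk <- if (nrow(pairs) == 0) {
    # empty pairing is allowed but flagged through the matched count
    list(rmse = NA_real_, std = NA_real_)
  } else {
    peak_rmse_std(pairs)
  }
  tibble(
    joint = joint, r2 = r2, rom = range_y,
    rmse = pk$rmse, nrmse = normalized(pk$rmse, range_y),
    std = pk$std, nstd = normalized(pk$std, range_y),
    n_peaks_matched = nrow(pairs),
    n_peaks_unmatched = attr(pairs, "n_unmatched_actual") +
      attr(pairs, "n_unmatched_pred")
  )
}

#' Interpretation label for a correlation-scale value
#'
#' Bins: 0-0.10 negligible, 0.10-0.39 weak, 0.40-0.69 moderate,
#' 0.70-0.89 strong, 0.90-1.00 very strong.
#'
#' @param r Correlation-scale values in `[0, 1]` (mean R2 here).
#' @return Character labels.
#' @export
schober_label <- function(r) {
  as.character(cut(
    abs(r),
    breaks = c(-Inf, 0.10, 0.40, 0.70, 0.90, Inf),
    labels = c("negligible", "weak", "moderate", "strong", "very strong"),
    right = FALSE
  ))
}

#' Paired comparison of a metric between the two regressors
#'
#' Two-tailed paired t-test of accelerometer vs gyroscope values across
#' participants; significance at p < 0.05. When the metric is R2 the
#' group means also receive their correlation-strength labels.
#'
#' @param accel,gyro Equal-length paired per-participant metric values.
#' @param parameter Name of the metric being compared (e.g. `"r2"`).
#' @return A one-row tibble with group means/SDs, `t_statistic`, `df`,
#'   `p_value`, `significant`, and Schober labels for R2.
#' @export
paired_comparison <- function(accel, gyro, parameter = "metric") {
  if (length(accel) != length(gyro) || length(accel) < 2) {
    stop_arg("need equal-length paired samples with n >= 2")
  }
  d <- accel - gyro
  if (sd(d) == 0) {
    stop_metric("degenerate paired test: all differences identical")
  }
  tt <- t.test(accel, gyro, paired = TRUE)
  is_r2 <- identical(parameter, "r2")
  tibble(
    parameter = parameter,
    mean_accel = mean(accel), sd_accel = sd(accel),
    mean_gyro = mean(gyro), sd_gyro = sd(gyro),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < 0.05,
    schober_accel = if (is_r2) schober_label(mean(accel)) else NA_character_,
    schober_gyro = if (is_r2) schober_label(mean(gyro)) else NA_character_
  )
}
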
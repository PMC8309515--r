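# Signal preparation: clock synchronization from foot-strike pulses,
# anti-aliased resampling to the kinematics rate, regressor channel
# construction, steady-state segmentation and sliding-window framing.

#' Recover the clock offset between sensor and kinematics systems
#'
#' Both recordings carry three synchronization foot strikes in their
#' first 10 s. Each side's strike onsets are detected from the largest
#' sample-to-sample jumps of its marker channel (accelerometer y for
#' the sensor, the knee-angle derivative for the kinematics), and the
#' offset is the mean pairwise difference of the two onset triplets.
#' Subtracting the returned offset from the sensor clock aligns the two
#' systems to within one sample at 100 Hz.
#'
#' @param sensor A [sensor_recording()] (or any tibble with `t` and
#'   `ay`).
#' @param kin A [kinematics_recording()] (or any tibble with `t` and
#'   `knee`).
#' @return The clock offset in seconds (sensor minus kinematics).
#' @export
synchronize <- function(sensor, kin) {
  ts <- detect_sync_onsets(sensor$t, marker_channel(sensor), "sensor")
  tk <- detect_sync_onsets(kin$t, marker_channel(kin), "kinematics")
  mean(ts - tk)
}

marker_channel <- function(rec) {
  if (!is.null(rec[["ay"]])) rec$ay
  else if (!is.null(rec[["knee"]])) rec$knee
  else stop_arg("recording has neither an 'ay' nor a 'knee' channel")
}

# Onset times of the three spike pulses in the first 10 s of a trace.
# Pulse edges dominate the absolute first difference; above-threshold
# samples are grouped into events separated by > 0.2 s.
detect_sync_onsets <- function(t, x, side, window = 10, min_gap = 0.2) {
  keep <- t < t[1] + window
  t <- t[keep]
  x <- x[keep]
  d <- abs(diff(x))
  thr <- max(median(d) + 10 * mad(d), 0.5 * max(d))
  idx <- which(d > thr)
  if (length(idx) == 0) {
    abort(sprintf("no synchronization spikes detected on the %s side", side),
          class = "gaitcnn_sync_error")
  }
  t_edge <- t[idx + 1L]
  grp <- cumsum(c(TRUE, diff(t_edge) > min_gap))
  onsets <- vapply(split(t_edge, grp), min, 0)
  if (length(onsets) < 3) {
    abort(sprintf(
      "only %d synchronization spike(s) detected on the %s side (need 3)",
      length(onsets), side
    ), class = "gaitcnn_sync_error")
  }
  sort(onsets)[1:3]
}

#' Shift a sensor recording onto the kinematics clock
#'
#' @param sensor A [sensor_recording()].
#' @param offset Clock offset in seconds from [synchronize()].
#' @return The recording with `t` and its sync events shifted by
#'   `-offset`.
#' @export
apply_clock_offset <- function(sensor, offset) {
  m <- recording_meta(sensor)
  sensor_recording(
    sensor$t - offset, sensor$ax, sensor$ay, sensor$az,
    sensor$gx, sensor$gy, sensor$gz,
    participant_id = m$participant_id, surface = m$surface,
    speed = m$speed, sample_rate = m$sample_rate,
    sync_events = m$sync_events - offset
  )
}

#' Resample a sensor recording to the kinematics rate
#'
#' Applies a zero-phase low-pass filter (4th-order Butterworth, 40 Hz
#' cutoff, forward-backward with reflective padding so no phase shift
#' or edge transient is introduced) and then decimates. Gait content
#' lives below ~20 Hz, so the passband is untouched.
#'
#' @param sensor A [sensor_recording()].
#' @param target_rate Output rate in Hz (default 100); the input rate
#'   must be an integer multiple of it.
#' @param cutoff Anti-alias cutoff in Hz.
#' @return A [sensor_recording()] at `target_rate`, with timestamps
#'   taken from the retained input samples.
#' @export
resample_to_target_rate <- function(sensor, target_rate = 100, cutoff = 40) {
  m <- recording_meta(sensor)
  rate <- m$sample_rate
  if (rate %% target_rate != 0) {
    stop_arg("sample rate %g Hz is not an integer multiple of %g Hz",
             rate, target_rate)
  }
  factor <- rate %/% target_rate
  if (factor == 1L) return(sensor)
  n_out <- nrow(sensor) %/% factor
  idx <- seq(1L, by = factor, length.out = n_out)
  cols <- c("ax", "ay", "az", "gx", "gy", "gz")
  filtered <- lapply(sensor[cols], lowpass_zero_phase, rate = rate,
                     cutoff = cutoff)
  sensor_recording(
    sensor$t[idx],
    filtered$ax[idx], filtered$ay[idx], filtered$az[idx],
    filtered$gx[idx], filtered$gy[idx], filtered$gz[idx],
    participant_id = m$participant_id, surface = m$surface,
    speed = m$speed, sample_rate = target_rate,
    sync_events = m$sync_events
  )
}

# Zero-phase Butterworth low-pass with reflective padding (1 s or the
# signal length, whichever is smaller) to suppress edge transients.
lowpass_zero_phase <- function(x, rate, cutoff) {
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1L, as.integer(rate))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)]
}

#' Build the univariate regressor channel
#'
#' The accelerometer regressor is the y-component (approximately the
#' tibial axis) unchanged; the gyroscope regressor is the resultant of
#' the x and z components, sqrt(gx^2 + gz^2), scaled down by 100 to a
#' numerical range similar to the accelerations.
#'
#' @param sensor A [sensor_recording()] already at 100 Hz.
#' @param channel `"accel_y"` or `"gyro_resultant_xz"`.
#' @return A `regressor_series` tibble with columns `t` and `x`,
#'   carrying the session metadata and the channel as attributes.
#' @export
build_regressor <- function(sensor,
                            channel = c("accel_y", "gyro_resultant_xz")) {
  channel <- match.arg(channel)
  m <- recording_meta(sensor)
  x <- switch(channel,
    accel_y = sensor$ay,
    gyro_resultant_xz = sqrt(sensor$gx^2 + sensor$gz^2) / 100
  )
  out <- new_recording(tibble(t = sensor$t, x = x), "regressor_series",
                       m$participant_id, m$surface, m$speed, m$sample_rate,
                       m$sync_events)
  attr(out, "channel") <- channel
  out
}

#' Steady-state segmentation plan for a session
#'
#' A 3-minute session drops a 15 s ingress buffer at each end and
#' splits the remaining 2.5 min into 60, 60 and 30 s sets, of which the
#' first 60 s set is used. Other session lengths scale every piece
#' proportionally.
#'
#' @param session_duration Session length in seconds.
#' @param buffer_head,buffer_tail,split,selected Override individual
#'   pieces (seconds; `selected` indexes into `split`). The pieces must
#'   sum to `session_duration`.
#' @return A `segmentation_plan` list.
#' @export
segmentation_plan <- function(session_duration = 180,
                              buffer_head = NULL, buffer_tail = NULL,
                              split = NULL, selected = 1L) {
  scale <- session_duration / 180
  buffer_head <- buffer_head %||% (15 * scale)
  buffer_tail <- buffer_tail %||% (15 * scale)
  split <- split %||% (c(60, 60, 30) * scale)
  total <- buffer_head + buffer_tail + sum(split)
  if (abs(total - session_duration) > 1e-6) {
    stop_arg("plan pieces sum to %g s, not the session duration %g s",
             total, session_duration)
  }
  if (selected < 1 || selected > length(split)) {
    stop_arg("selected segment index out of range")
  }
  structure(
    list(session_duration = session_duration, buffer_head = buffer_head,
         buffer_tail = buffer_tail, split = split,
         selected = as.integer(selected)),
    class = "segmentation_plan"
  )
}

#' Extract the selected steady-state segment of a session series
#'
#' @param series A `regressor_series`, [kinematics_recording()] or any
#'   uniformly sampled tibble with a `t` column and a `sample_rate`
#'   attribute.
#' @param plan A [segmentation_plan()]; its pieces must cover the
#'   series' measured duration (0.5 s slack absorbs the few samples
#'   trimmed during clock alignment).
#' @return The rows of `series` inside the selected segment, metadata
#'   preserved.
#' @export
segment_session <- function(series, plan = segmentation_plan()) {
  rate <- attr(series, "sample_rate")
  measured <- nrow(series) / rate
  if (abs(measured - plan$session_duration) > 0.5) {
    stop_arg("series duration is %.2f s but the plan expects %g s",
             measured, plan$session_duration)
  }
  start <- plan$buffer_head +
    if (plan$selected > 1) sum(plan$split[seq_len(plan$selected - 1)]) else 0
  len <- plan$split[plan$selected]
  t_rel <- series$t - series$t[1]
  keep <- which(t_rel >= start - 1e-9 & t_rel < start + len - 1e-9)
  out <- series[keep, ]
  for (a in c(REC_META, "channel")) attr(out, a) <- attr(series, a)
  class(out) <- class(series)
  out
}

#' Cut a regressor/target pair into overlapping training frames
#'
#' Frame `i` covers samples `i .. i+59` (0.6 s at 100 Hz) and its
#' target is the angle at sample `i+30`, the centre of the window;
#' edge positions lacking a full window are dropped, so a length-`L`
#' series yields `L - 59` frames at stride 1.
#'
#' @param regressor A `regressor_series` segment.
#' @param target A kinematics segment on the identical 100 Hz grid.
#' @param joint `"knee"` or `"hip"`.
#' @return A `frame_set`: list with `X` (N x 60 matrix), `y` (length-N
#'   targets, degrees), `center_times`, `joint`, `channel` and a
#'   provenance `manifest` tibble.
#' @export
make_frames <- function(regressor, target, joint = c("knee", "hip")) {
  joint <- match.arg(joint)
  L <- nrow(regressor)
  if (L < 60) stop_arg("need at least 60 samples to build one frame, got %d", L)
  if (nrow(target) != L || max(abs(regressor$t - target$t)) > 1e-6) {
    stop_arg("regressor and target must share the same time grid")
  }
  X <- stats::embed(regressor$x, 60)[, 60:1, drop = FALSE]
  idx <- seq_len(L - 59L) + 30L
  m <- recording_meta(regressor)
  new_frame_set(
    X = X, y = target[[joint]][idx], center_times = target$t[idx],
    joint = joint, channel = attr(regressor, "channel"),
    manifest = tibble(
      participant_id = m$participant_id, surface = m$surface,
      speed = m$speed, n = L - 59L
    )
  )
}

new_frame_set <- function(X, y, center_times, joint, channel, manifest) {
  structure(
    list(X = X, y = y, center_times = center_times, joint = joint,
         channel = channel, manifest = manifest),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames x %d samples | joint %s | channel %s\n",
              nrow(x$X), ncol(x$X), x$joint, x$channel))
  print(x$manifest)
  invisible(x)
}

#' Number of frames in a frame set
#' @param frames A `frame_set`.
#' @return Integer count.
#' @export
n_frames <- function(frames) nrow(frames$X)

#' Pool several frame sets into one training set
#'
#' Frames are concatenated in the order given (the study runner passes
#' treadmill segments in ascending speed order); windows never span the
#' splice points because framing happens per segment before pooling.
#'
#' @param frame_sets A list of `frame_set` objects with identical joint
#'   and channel.
#' @return One pooled `frame_set` whose manifest stacks the sources.
#' @export
bind_frame_sets <- function(frame_sets) {
  stopifnot(length(frame_sets) >= 1)
  joint <- unique(vapply(frame_sets, `[[`, "", "joint"))
  channel <- unique(vapply(frame_sets, `[[`, "", "channel"))
  if (length(joint) != 1 || length(channel) != 1) {
    stop_arg("frame sets to pool must share one joint and one channel")
  }
  new_frame_set(
    X = do.call(rbind, lapply(frame_sets, `[[`, "X")),
    y = unlist(lapply(frame_sets, `[[`, "y"), use.names = FALSE),
    center_times = unlist(lapply(frame_sets, `[[`, "center_times"),
                          use.names = FALSE),
    joint = joint, channel = channel,
    manifest = bind_rows(lapply(frame_sets, `[[`, "manifest"))
  )
}

#' Prepare one session end-to-end into a frame set
#'
#' Chains the full preprocessing of one paired recording: recover the
#' clock offset from the sync pulses, shift the sensor clock, low-pass
#' and decimate to 100 Hz, build the requested regressor channel,
#' interpolate it onto the kinematics grid, cut the steady-state
#' segment from both series and frame them.
#'
#' @param sensor,kin The raw paired recordings of one session.
#' @param channel Regressor channel.
#' @param joint Target joint.
#' @param plan A [segmentation_plan()] matching the session length.
#' @return A `frame_set`.
#' @export
prepare_frames <- function(sensor, kin,
                           channel = c("accel_y", "gyro_resultant_xz"),
                           joint = c("knee", "hip"),
                           plan = segmentation_plan()) {
  channel <- match.arg(channel)
  joint <- match.arg(joint)
  offset <- synchronize(sensor, kin)
  aligned <- apply_clock_offset(sensor, offset)
  low <- resample_to_target_rate(aligned)
  reg <- build_regressor(low, channel)
  pair <- align_series(reg, kin)
  make_frames(segment_session(pair$regressor, plan),
              segment_session(pair$kinematics, plan), joint)
}

# Interpolate the regressor onto the kinematics grid over their common
# time span; both outputs share the identical grid afterwards.
align_series <- function(regressor, kin) {
  lo <- max(min(regressor$t), min(kin$t))
  hi <- min(max(regressor$t), max(kin$t))
  keep <- which(kin$t >= lo - 1e-9 & kin$t <= hi + 1e-9)
  kin_out <- kin[keep, ]
  for (a in REC_META) attr(kin_out, a) <- attr(kin, a)
  class(kin_out) <- class(kin)
  x_i <- approx(regressor$t, regressor$x, xout = kin_out$t, rule = 2)$y
  m <- recording_meta(regressor)
  reg_out <- new_recording(tibble(t = kin_out$t, x = x_i), "regressor_series",
                           m$participant_id, m$surface, m$speed,
                           recording_meta(kin)$sample_rate, m$sync_events)
  attr(reg_out, "channel") <- attr(regressor, "channel")
  list(regressor = reg_out, kinematics = kin_out)
}
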
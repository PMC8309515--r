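# Synthetic running-gait simulator.
#
# Running kinematics are emulated as periodic per-stride waveforms on a
# jittered stride grid: the knee flexion curve carries a small stance
# peak followed by a large swing peak in every cycle, the hip flexion
# curve a single flexion peak late in swing. The tibia IMU channels are
# deterministic functionals of the knee-driven shank shape signal (gyro
# proportional to its angular velocity, accelerometer to its second
# derivative plus a constant gravity projection), attenuated by the
# running surface and corrupted by Gaussian sensor noise.

#' Sample a synthetic cohort of runners
#'
#' Draws one participant profile per runner: stride cadence and its
#' speed dependence, knee/hip waveform landmarks (degrees), the
#' deterministic IMU coupling gains, sensor noise levels and stride
#' timing jitter. All draws come from truncated normal distributions
#' around recreational-runner values, so every profile satisfies the
#' physiological orderings (stance peak below swing peak, minima below
#' peaks).
#'
#' @param n_participants Number of runners (>= 1).
#' @param seed Master seed; the cohort is a deterministic function of it.
#' @return A tibble with one row per participant and columns
#'   `participant_id`, `cadence_base` (strides/min at 2.5 m/s),
#'   `cadence_speed_slope` (strides/min per m/s), `knee_swing_peak`,
#'   `knee_stance_peak`, `knee_min`, `hip_peak`, `hip_min` (degrees),
#'   `coupling_gain_accel` ((m/s^2) per degree),
#'   `coupling_gain_gyro` ((deg/s) per degree), `gravity_y` (m/s^2,
#'   the per-participant gravity projection set by sensor mounting
#'   tilt), `gyro_mount_angle` (radians; rotates angular velocity
#'   between the x and z gyro axes -- their resultant is mounting
#'   invariant, which is why that channel is used), `noise_sd_accel`
#'   (m/s^2), `noise_sd_gyro` (deg/s), `stride_jitter_cv`,
#'   `hip_amp_cv` (per-stride hip amplitude variability),
#'   `hip_drift_sd` (degrees of slow hip baseline wander, emulating the
#'   offset problems that make hip angles harder to predict from a
#'   shank-mounted sensor) and `rng_seed`.
#' @export
#' @examples
#' make_cohort(3, seed = 1)
make_cohort <- function(n_participants, seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop_arg("n_participants must be a positive integer")
  }
  n <- as.integer(n_participants)
  withr::with_seed(as.integer(seed), {
    tibble(
      participant_id = sprintf("P%02d", seq_len(n)),
      cadence_base = rnorm_trunc(n, 85, 3, 75, 95),
      cadence_speed_slope = rnorm_trunc(n, 4, 1, 1, 7),
      knee_swing_peak = rnorm_trunc(n, 105, 7, 85, 125),
      knee_stance_peak = rnorm_trunc(n, 40, 4, 28, 55),
      knee_min = rnorm_trunc(n, 12, 3, 4, 22),
      hip_peak = rnorm_trunc(n, 42, 5, 28, 58),
      hip_min = rnorm_trunc(n, -18, 4, -30, -6),
      coupling_gain_accel = rnorm_trunc(n, 0.005, 1e-3, 0.003, 0.007),
      coupling_gain_gyro = rnorm_trunc(n, 1.0, 0.2, 0.6, 1.4),
      gravity_y = runif(n, 8.8, 9.8),
      gyro_mount_angle = runif(n, 0.5, 1.0),
      noise_sd_accel = rnorm_trunc(n, 0.8, 0.1, 0.5, 1.1),
      noise_sd_gyro = rnorm_trunc(n, 8, 1, 5, 11),
      stride_jitter_cv = runif(n, 0.01, 0.03),
      hip_amp_cv = runif(n, 0.08, 0.15),
      hip_drift_sd = runif(n, 4, 7),
      rng_seed = vapply(seq_len(n), function(i) child_seed(seed, i), 1L)
    )
  })
}

# One-sided-safe truncated normal via inverse-CDF; one uniform per draw.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Describe how a running surface filters the IMU signals
#'
#' The treadmill deck is compliant and shock absorbing, so the dynamic
#' (non-gravity) part of the accelerometer signal is attenuated relative
#' to level ground, and slightly noisier through belt vibration; the
#' gyroscope, which senses segment rotation rather than impact, is left
#' essentially untouched. Attenuation factors multiply the dynamic
#' signal component.
#'
#' @param surface `"treadmill"` or `"level_ground"`.
#' @param accel_attenuation Multiplicative factor in (0, 1] on the
#'   dynamic accelerometer component. Default 0.85 for treadmill, 1 for
#'   level ground: the compliant deck absorbs part of the impact
#'   acceleration but leaves it the dominant signal.
#' @param gyro_attenuation Factor in (0, 1] on the gyroscope channels;
#'   default 1 (surface-independent) for both surfaces.
#' @param extra_accel_noise_sd Additional accelerometer noise (m/s^2)
#'   from belt vibration, default 1.0 on the treadmill and 0 on level
#'   ground.
#' @return A `surface_model` list.
#' @export
surface_model <- function(surface = c("treadmill", "level_ground"),
                          accel_attenuation = NULL,
                          gyro_attenuation = 1,
                          extra_accel_noise_sd = NULL) {
  surface <- match.arg(surface)
  accel_attenuation <- accel_attenuation %||%
    if (surface == "treadmill") 0.85 else 1
  extra_accel_noise_sd <- extra_accel_noise_sd %||%
    if (surface == "treadmill") 1.0 else 0
  if (accel_attenuation <= 0 || accel_attenuation > 1 ||
      gyro_attenuation <= 0 || gyro_attenuation > 1) {
    stop_arg("attenuation factors must lie in (0, 1]")
  }
  if (gyro_attenuation < accel_attenuation) {
    stop_arg("gyro_attenuation must be >= accel_attenuation")
  }
  structure(
    list(surface = surface,
         accel_attenuation = accel_attenuation,
         gyro_attenuation = gyro_attenuation,
         extra_accel_noise_sd = extra_accel_noise_sd),
    class = "surface_model"
  )
}

# Jittered stride grid: boundary times of successive strides covering
# [0, duration], plus per-stride hip amplitude multipliers.
stride_grid <- function(duration, period, jitter_cv, hip_amp_cv) {
  n_max <- ceiling(duration / (period * 0.7)) + 3L
  periods <- period * pmax(0.6, 1 + jitter_cv * rnorm(n_max))
  tau <- c(0, cumsum(periods))
  keep <- seq_len(which(tau > duration)[1])
  hmul <- pmin(1.3, pmax(0.7, 1 + hip_amp_cv * rnorm(length(keep))))
  list(tau = tau[keep], hmul = hmul)
}

# Piecewise-linear stride phase in [0, 1) at times t.
stride_phase <- function(t, tau) {
  k <- findInterval(t, tau, rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1L), length(tau) - 1L)
  list(k = k, phi = (t - tau[k]) / (tau[k + 1L] - tau[k]))
}

# Gaussian bump in phase; tails vanish at the stride boundaries.
phase_bump <- function(phi, center, width) exp(-0.5 * ((phi - center) / width)^2)

KNEE_STANCE_PHASE <- 0.18
KNEE_SWING_PHASE <- 0.72
HIP_PEAK_PHASE <- 0.85
SYNC_TIMES <- c(2.0, 3.5, 5.0)   # true times (s) of the three foot strikes
                                 # (scaled down with sub-3-min sessions so
                                 # they stay inside the scaled ingress buffer)
SYNC_WIDTH <- 0.04               # pulse width (s)

knee_curve <- function(phi, knee_min, stance_peak, swing_peak) {
  knee_min +
    (stance_peak - knee_min) * phase_bump(phi, KNEE_STANCE_PHASE, 0.07) +
    (swing_peak - knee_min) * phase_bump(phi, KNEE_SWING_PHASE, 0.11)
}

hip_curve <- function(phi, hmul_k, hip_min, hip_peak) {
  hip_min + hmul_k * (hip_peak - hip_min) *
    0.5 * (1 + cos(2 * pi * (phi - HIP_PEAK_PHASE)))
}

#' Simulate one running session for a participant
#'
#' Produces the paired raw recordings of one trial: the 500 Hz tibia
#' IMU trace and the 100 Hz hip/knee kinematics trace. Both carry three
#' synchronization foot-strike pulses in their first 10 s at identical
#' true times; the sensor clock is offset from the kinematics clock by
#' a random lag drawn uniformly from [0, 0.5] s, which
#' [synchronize()] recovers downstream.
#'
#' @param profile A one-row tibble (a row of [make_cohort()]).
#' @param surface A [surface_model()] (or a surface name, in which case
#'   the default model for that surface is used).
#' @param speed Running speed in m/s (> 0).
#' @param duration Session length in seconds (>= 30).
#' @param seed Session seed; by default derived from the profile's
#'   `rng_seed`, the surface and the speed, so repeated calls are
#'   bit-identical.
#' @return A list with elements `sensor` (a [sensor_recording()]) and
#'   `kinematics` (a [kinematics_recording()]).
#' @export
simulate_session <- function(profile, surface, speed, duration = 180,
                             seed = NULL) {
  profile <- as.list(profile)
  if (is.character(surface)) surface <- surface_model(surface)
  if (!inherits(surface, "surface_model")) {
    stop_arg("surface must be a surface_model or surface name")
  }
  if (!is.numeric(speed) || speed <= 0) stop_arg("speed must be > 0")
  if (!is.numeric(duration) || duration < 30) {
    stop_arg("duration must be at least 30 s (got %g)", duration)
  }
  seed <- seed %||% child_seed(profile$rng_seed, surface$surface,
                               round(speed * 100), round(duration))
  rate_sens <- 500
  rate_kin <- 100
  cadence <- profile$cadence_base +
    profile$cadence_speed_slope * (speed - 2.5)
  period <- 60 / cadence

  sync_times <- SYNC_TIMES * min(1, duration / 180)
  withr::with_seed(as.integer(seed), {
    grid <- stride_grid(duration, period, profile$stride_jitter_cv,
                        profile$hip_amp_cv)
    clock_offset <- runif(1, 0, 0.5)

    t_s <- seq(0, duration - 1 / rate_sens, by = 1 / rate_sens)
    t_k <- seq(0, duration - 1 / rate_kin, by = 1 / rate_kin)

    ph_s <- stride_phase(t_s, grid$tau)
    ph_k <- stride_phase(t_k, grid$tau)

    shank_s <- knee_curve(ph_s$phi, profile$knee_min,
                          profile$knee_stance_peak, profile$knee_swing_peak)
    knee_k <- knee_curve(ph_k$phi, profile$knee_min,
                         profile$knee_stance_peak, profile$knee_swing_peak)
    hip_k <- hip_curve(ph_k$phi, grid$hmul[ph_k$k],
                       profile$hip_min, profile$hip_peak) +
      hip_drift(t_k, duration, profile$hip_drift_sd %||% 0)

    omega <- profile$coupling_gain_gyro * num_deriv(shank_s, 1 / rate_sens)
    a_dyn <- profile$coupling_gain_accel *
      num_deriv(num_deriv(shank_s, 1 / rate_sens), 1 / rate_sens)

    n_s <- length(t_s)
    g_att <- surface$gyro_attenuation
    a_att <- surface$accel_attenuation
    sd_g <- profile$noise_sd_gyro
    sd_a <- sqrt(profile$noise_sd_accel^2 + surface$extra_accel_noise_sd^2)

    # mounting geometry: the x/z gyro split depends on how the sensor
    # sits on the shank, but sqrt(gx^2 + gz^2) recovers |omega| for any
    # mounting angle; the accelerometer's gravity offset does depend on
    # the mounting tilt, one reason it transfers worse across runners
    alpha <- profile$gyro_mount_angle %||% 0.64
    g_y <- profile$gravity_y %||% 9.6
    gx <- cos(alpha) * omega * g_att + noise_vec(n_s, sd_g)
    gy <- 0.1 * omega * g_att + noise_vec(n_s, sd_g)
    gz <- sin(alpha) * omega * g_att + noise_vec(n_s, sd_g)
    ax <- 0.3 * a_dyn * a_att + noise_vec(n_s, sd_a)
    ay <- g_y + a_dyn * a_att + noise_vec(n_s, sd_a)
    az <- 0.4 * a_dyn * a_att + noise_vec(n_s, sd_a)

    # Synchronization pulses at identical true times on both systems;
    # amplitude 5x the marker channel's peak deviation so the strike
    # edges dominate any within-gait transient.
    amp_ay <- 5 * max(abs(ay - median(ay)))
    amp_knee <- 5 * max(abs(knee_k - median(knee_k)))
    for (e in sync_times) {
      ay[t_s >= e & t_s < e + SYNC_WIDTH] <-
        ay[t_s >= e & t_s < e + SYNC_WIDTH] + amp_ay
      knee_k[t_k >= e & t_k < e + SYNC_WIDTH] <-
        knee_k[t_k >= e & t_k < e + SYNC_WIDTH] + amp_knee
    }

    sens <- sensor_recording(
      t = t_s + clock_offset, ax = ax, ay = ay, az = az,
      gx = gx, gy = gy, gz = gz,
      participant_id = profile$participant_id, surface = surface$surface,
      speed = speed, sample_rate = rate_sens,
      sync_events = sync_times + clock_offset
    )
    kin <- kinematics_recording(
      t = t_k, knee = knee_k, hip = hip_k,
      participant_id = profile$participant_id, surface = surface$surface,
      speed = speed, sample_rate = rate_kin, sync_events = sync_times
    )
    list(sensor = sens, kinematics = kin)
  })
}

noise_vec <- function(n, sd) if (sd > 0) rnorm(n, 0, sd) else numeric(n)

# Slow baseline wander of the hip angle (spline through knots every
# ~5 s): measurement offset drift that no 0.6 s sensor window can
# explain, capping hip predictability below the knee's.
hip_drift <- function(t, duration, sd) {
  if (sd <= 0) return(numeric(length(t)))
  knots <- seq(0, duration, by = 5)
  if (length(knots) < 4) knots <- seq(0, duration, length.out = 4)
  vals <- rnorm(length(knots), 0, sd)
  stats::spline(knots, vals, xout = t)$y
}

#' Simulate the full study protocol for a cohort
#'
#' Each participant runs four treadmill sessions (2.0, 2.5, 3.0,
#' 3.5 m/s) and one level-ground session at a preferred speed drawn
#' from N(2.44, 0.34) m/s truncated to (1.5, 3.5).
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param seed Study seed (session seeds and preferred speeds derive
#'   from it).
#' @param session_duration Length of every session in seconds
#'   (default 180; shorter values give proportionally scaled smoke
#'   studies).
#' @param treadmill_speeds Belt speeds in m/s.
#' @param treadmill_model,level_model Surface models for the two
#'   surfaces; defaults attenuate the treadmill accelerometer to 0.75.
#' @return A tibble with one row per session: `participant_id`,
#'   `surface`, `speed`, `duration`, and list-columns `sensor` and
#'   `kinematics` holding the recordings.
#' @export
simulate_study <- function(cohort, seed = 1L, session_duration = 180,
                           treadmill_speeds = c(2.0, 2.5, 3.0, 3.5),
                           treadmill_model = surface_model("treadmill"),
                           level_model = surface_model("level_ground")) {
  if (nrow(cohort) < 1) stop_arg("cohort must be nonempty")
  preferred <- withr::with_seed(
    child_seed(seed, "preferred_speed"),
    rnorm_trunc(nrow(cohort), 2.44, 0.34, 1.5, 3.5)
  )
  sessions <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    prof <- cohort[i, ]
    speeds <- c(treadmill_speeds, preferred[i])
    surfaces <- c(rep("treadmill", length(treadmill_speeds)), "level_ground")
    purrr::map_dfr(seq_along(speeds), function(j) {
      model <- if (surfaces[j] == "treadmill") treadmill_model else level_model
      ses <- simulate_session(
        prof, model, speeds[j], session_duration,
        seed = child_seed(seed, i, surfaces[j], round(speeds[j] * 1000))
      )
      tibble(
        participant_id = prof$participant_id,
        surface = surfaces[j], speed = speeds[j],
        duration = session_duration,
        sensor = list(ses$sensor), kinematics = list(ses$kinematics)
      )
    })
  })
  sessions
}

#' Sample level-ground preferred running speeds
#'
#' Exposed for calibration checks: draws from the preferred-speed
#' distribution N(2.44, 0.34) m/s truncated to (1.5, 3.5).
#'
#' @param n Number of draws.
#' @param seed Seed.
#' @return Numeric vector of speeds (m/s).
#' @export
sample_preferred_speeds <- function(n, seed = 1L) {
  withr::with_seed(as.integer(seed), rnorm_trunc(n, 2.44, 0.34, 1.5, 3.5))
}
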
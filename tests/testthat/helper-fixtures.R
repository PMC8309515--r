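# Shared fixtures: all synthetic, generated at test time.

# A deterministic profile with sensor noise switched off (stride jitter
# and hip drift stay at their defaults unless overridden).
quiet_profile <- function(seed = 2, ...) {
  prof <- make_cohort(1, seed = seed)
  over <- list(...)
  for (nm in names(over)) prof[[nm]] <- over[[nm]]
  prof$noise_sd_accel <- over$noise_sd_accel %||% 0
  prof$noise_sd_gyro <- over$noise_sd_gyro %||% 0
  prof
}

`%||%` <- function(x, y) if (is.null(x)) y else x

quiet_surface <- function(surface, accel_attenuation = 1) {
  surface_model(surface, accel_attenuation = accel_attenuation,
                extra_accel_noise_sd = 0)
}

# Kinematics recording built directly from vectors on the 100 Hz grid.
kin_from_vectors <- function(knee, hip = knee, rate = 100) {
  n <- length(knee)
  kinematics_recording(
    t = seq(0, by = 1 / rate, length.out = n), knee = knee, hip = hip,
    participant_id = "T01", surface = "level_ground", speed = 2.5,
    sample_rate = rate
  )
}

# Regressor series built directly from a vector.
reg_from_vector <- function(x, rate = 100, channel = "accel_y") {
  n <- length(x)
  out <- gaitcnn:::new_recording(
    tibble::tibble(t = seq(0, by = 1 / rate, length.out = n), x = x),
    "regressor_series", "T01", "level_ground", 2.5, rate, numeric(0)
  )
  attr(out, "channel") <- channel
  out
}

# Frame set straight from a matrix (for network-level tests).
frames_from_matrix <- function(X, y, joint = "knee", channel = "accel_y") {
  gaitcnn:::new_frame_set(
    X = X, y = y, center_times = seq_len(nrow(X)) / 100,
    joint = joint, channel = channel,
    manifest = tibble::tibble(participant_id = "T01",
                              surface = "treadmill", speed = 2.5,
                              n = nrow(X))
  )
}

# Train-on-own-treadmill / test-on-level-ground evaluation for one
# profile, used by the learning-sanity checks. Returns the metrics row.
intra_eval <- function(prof, channel, joint, duration, epochs, fit_seed,
                       treadmill = quiet_surface("treadmill"),
                       level = quiet_surface("level_ground"),
                       batch_size = 512L) {
  plan <- segmentation_plan(duration)
  train <- bind_frame_sets(lapply(c(2.0, 2.5, 3.0, 3.5), function(sp) {
    s <- simulate_session(prof, treadmill, sp, duration)
    prepare_frames(s$sensor, s$kinematics, channel, joint, plan)
  }))
  s2 <- simulate_session(prof, level, 2.4, duration)
  test <- prepare_frames(s2$sensor, s2$kinematics, channel, joint, plan)
  off <- synchronize(s2$sensor, s2$kinematics)
  low <- resample_to_target_rate(apply_clock_offset(s2$sensor, off))
  pair <- gaitcnn:::align_series(build_regressor(low, channel),
                                 s2$kinematics)
  kin_seg <- segment_session(pair$kinematics, plan)
  fit <- fit_cnn(train, cnn_config(epochs = epochs, rng_seed = fit_seed,
                                   batch_size = batch_size))
  angle_metrics(kin_seg, predict(fit, test), joint)
}

# The smoke-scale directional study (4 runners, 30 s sessions, knee,
# both channels) is reused across tests; memoised per master seed.
smoke_study_cache <- local({
  cache <- list()
  function(master_seed, schemes = "intra") {
    key <- paste0(master_seed, "-", paste(schemes, collapse = "+"))
    if (is.null(cache[[key]])) {
      # batch scaled with the training-set size so the optimizer keeps
      # its steps-per-epoch at smoke scale (512 * 3764/23941 ~ 80)
      cfg <- study_config(
        n_participants = 4, master_seed = master_seed, joints = "knee",
        schemes = schemes, session_duration = 30, epochs = 5,
        batch_size = 128L
      )
      cache[[key]] <<- run_study(cfg)
    }
    cache[[key]]
  }
})
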
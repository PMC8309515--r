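# Recording containers: tibbles carrying session metadata as attributes.

REC_META <- c("participant_id", "surface", "speed", "sample_rate", "sync_events")

new_recording <- function(df, class, participant_id, surface, speed,
                          sample_rate, sync_events) {
  out <- tibble::as_tibble(df)
  attr(out, "participant_id") <- participant_id
  attr(out, "surface") <- surface
  attr(out, "speed") <- speed
  attr(out, "sample_rate") <- sample_rate
  attr(out, "sync_events") <- sync_events
  class(out) <- c(class, class(out))
  out
}

#' Construct a raw tibia-IMU recording
#'
#' A tibble of tri-axial accelerations (m/s^2) and angular velocities
#' (deg/s) on a uniform time grid, carrying session metadata
#' (participant, surface, speed, sample rate, synchronization event
#' times) as attributes.
#'
#' @param t Time stamps in seconds, uniformly spaced.
#' @param ax,ay,az Accelerometer channels, m/s^2.
#' @param gx,gy,gz Gyroscope channels, deg/s.
#' @param participant_id Participant label.
#' @param surface `"treadmill"` or `"level_ground"`.
#' @param speed Belt or running speed, m/s.
#' @param sample_rate Sampling rate in Hz (500 for the raw sensor).
#' @param sync_events Times (s, in this recording's clock) of the three
#'   synchronization foot strikes.
#' @return A `sensor_recording` tibble with columns
#'   `t, ax, ay, az, gx, gy, gz`.
#' @export
sensor_recording <- function(t, ax, ay, az, gx, gy, gz,
                             participant_id, surface, speed,
                             sample_rate = 500, sync_events = numeric(0)) {
  lens <- lengths(list(ax, ay, az, gx, gy, gz))
  if (any(lens != length(t))) {
    stop_arg("all sensor channels must have the same length as t")
  }
  check_uniform_grid(t, sample_rate)
  new_recording(
    tibble(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz),
    "sensor_recording", participant_id, surface, speed, sample_rate,
    sync_events
  )
}

#' Construct a joint-kinematics recording
#'
#' Hip and knee sagittal flexion angles (degrees) sampled at 100 Hz,
#' with session metadata as attributes.
#'
#' @param t Time stamps in seconds, uniformly spaced.
#' @param knee,hip Flexion angles in degrees.
#' @inheritParams sensor_recording
#' @return A `kinematics_recording` tibble with columns `t, knee, hip`.
#' @export
kinematics_recording <- function(t, knee, hip,
                                 participant_id, surface, speed,
                                 sample_rate = 100, sync_events = numeric(0)) {
  if (length(knee) != length(t) || length(hip) != length(t)) {
    stop_arg("knee and hip must have the same length as t")
  }
  if (!all(is.finite(knee)) || !all(is.finite(hip))) {
    stop_arg("angle traces must be finite")
  }
  check_uniform_grid(t, sample_rate)
  new_recording(
    tibble(t = t, knee = knee, hip = hip),
    "kinematics_recording", participant_id, surface, speed, sample_rate,
    sync_events
  )
}

check_uniform_grid <- function(t, sample_rate) {
  if (length(t) >= 2) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - 1 / sample_rate)) > 1e-6) {
      stop_arg("t must be strictly increasing at 1/%g s spacing", sample_rate)
    }
  }
  invisible(t)
}

#' Session metadata of a recording or series
#'
#' @param x A `sensor_recording`, `kinematics_recording` or
#'   `regressor_series`.
#' @return A list with `participant_id`, `surface`, `speed`,
#'   `sample_rate` and `sync_events`.
#' @export
recording_meta <- function(x) {
  out <- lapply(REC_META, function(a) attr(x, a))
  names(out) <- REC_META
  out
}

#' @export
print.sensor_recording <- function(x, ...) {
  m <- recording_meta(x)
  cat(sprintf(
    "<sensor_recording> %s | %s @ %.2f m/s | %g Hz | %.1f s\n",
    m$participant_id, m$surface, m$speed, m$sample_rate,
    nrow(x) / m$sample_rate
  ))
  NextMethod()
}

#' @export
print.kinematics_recording <- function(x, ...) {
  m <- recording_meta(x)
  cat(sprintf(
    "<kinematics_recording> %s | %s @ %.2f m/s | %g Hz | %.1f s\n",
    m$participant_id, m$surface, m$speed, m$sample_rate,
    nrow(x) / m$sample_rate
  ))
  NextMethod()
}

#' Write a simulated session to CSV files with a JSON sidecar
#'
#' The sensor trace goes to `<stem>_sensor.csv` (columns
#' `t, ax, ay, az, gx, gy, gz`), the kinematics trace to
#' `<stem>_kinematics.csv` (columns `t, knee, hip`), and the shared
#' metadata to `<stem>_session.json`.
#'
#' @param session A list with elements `sensor` and `kinematics` as
#'   returned by [simulate_session()].
#' @param stem Path prefix for the three files.
#' @return Invisibly, the three paths written.
#' @export
write_session <- function(session, stem) {
  sensor_path <- paste0(stem, "_sensor.csv")
  kin_path <- paste0(stem, "_kinematics.csv")
  meta_path <- paste0(stem, "_session.json")
  utils::write.csv(as.data.frame(session$sensor), sensor_path,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(session$kinematics), kin_path,
                   row.names = FALSE)
  m <- recording_meta(session$sensor)
  meta <- list(
    participant_id = m$participant_id,
    surface = m$surface,
    speed = m$speed,
    sensor_sample_rate = m$sample_rate,
    kinematics_sample_rate = recording_meta(session$kinematics)$sample_rate,
    sensor_sync_events = m$sync_events,
    kinematics_sync_events = recording_meta(session$kinematics)$sync_events
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(sensor_path, kin_path, meta_path))
}

#' Read a session written by [write_session()]
#'
#' @param stem Path prefix used when writing.
#' @return A list with `sensor` and `kinematics` recordings.
#' @export
read_session <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_session.json"),
                              simplifyVector = TRUE)
  sens <- utils::read.csv(paste0(stem, "_sensor.csv"))
  kin <- utils::read.csv(paste0(stem, "_kinematics.csv"))
  list(
    sensor = sensor_recording(
      sens$t, sens$ax, sens$ay, sens$az, sens$gx, sens$gy, sens$gz,
      participant_id = meta$participant_id, surface = meta$surface,
      speed = meta$speed, sample_rate = meta$sensor_sample_rate,
      sync_events = meta$sensor_sync_events
    ),
    kinematics = kinematics_recording(
      kin$t, kin$knee, kin$hip,
      participant_id = meta$participant_id, surface = meta$surface,
      speed = meta$speed, sample_rate = meta$kinematics_sample_rate,
      sync_events = meta$kinematics_sync_events
    )
  )
}
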
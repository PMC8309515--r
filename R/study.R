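# Orchestration of the intraparticipant and leave-one-participant-out
# experiments: simulate a cohort, prepare frames, train one network per
# (scheme x joint x channel x fold), evaluate on level-ground running
# and compare the two regressors.

#' Configure a synthetic prediction study
#'
#' Defaults mirror the full protocol: 10 participants, four 3-minute
#' treadmill sessions (2.0-3.5 m/s) plus one 3-minute level-ground
#' session each, both regressor channels, both joints, both evaluation
#' schemes, and the full 50-epoch training recipe. Smoke studies shrink
#' `n_participants`, `session_duration` and `epochs` here without
#' touching any other default.
#'
#' @param n_participants Cohort size (>= 2 for the leave-one-out
#'   scheme).
#' @param master_seed One integer reproducing the whole study; cohort,
#'   sessions and every fold's training seed derive from it.
#' @param joints,channels,schemes Subsets of `c("knee", "hip")`,
#'   `c("accel_y", "gyro_resultant_xz")`, `c("intra", "inter")`.
#' @param session_duration Session length in seconds.
#' @param epochs,batch_size Training recipe overrides.
#' @param treadmill_model,level_model [surface_model()]s for the two
#'   surfaces.
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 10L, master_seed = 1L,
                         joints = c("knee", "hip"),
                         channels = c("accel_y", "gyro_resultant_xz"),
                         schemes = c("intra", "inter"),
                         session_duration = 180,
                         epochs = 50L, batch_size = 512L,
                         treadmill_model = surface_model("treadmill"),
                         level_model = surface_model("level_ground")) {
  joints <- match.arg(joints, several.ok = TRUE)
  channels <- match.arg(channels, several.ok = TRUE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (length(schemes) == 0) stop_arg("schemes must be nonempty")
  if ("inter" %in% schemes && n_participants < 2) {
    stop_arg("the leave-one-out scheme needs at least 2 participants")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         master_seed = as.integer(master_seed),
         joints = joints, channels = channels, schemes = schemes,
         session_duration = session_duration,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         treadmill_model = treadmill_model, level_model = level_model),
    class = "study_config"
  )
}

# Prepare every session of a simulated study once per channel:
# synchronize, resample, build the regressor, align and segment.
# Returns a tibble with list-columns reg_seg / kin_seg.
prepare_study <- function(sessions, channels, plan) {
  purrr::map_dfr(seq_len(nrow(sessions)), function(i) {
    sensor <- sessions$sensor[[i]]
    kin <- sessions$kinematics[[i]]
    offset <- synchronize(sensor, kin)
    low <- resample_to_target_rate(apply_clock_offset(sensor, offset))
    purrr::map_dfr(channels, function(ch) {
      pair <- align_series(build_regressor(low, ch), kin)
      tibble(
        participant_id = sessions$participant_id[i],
        surface = sessions$surface[i],
        speed = sessions$speed[i],
        channel = ch,
        clock_offset = offset,
        reg_seg = list(segment_session(pair$regressor, plan)),
        kin_seg = list(segment_session(pair$kinematics, plan))
      )
    })
  })
}

# Pooled training frames for a set of participants: treadmill segments
# in ascending participant then ascending speed order, framed per
# segment so no window crosses a splice.
training_frames <- function(prepared, participants, channel, joint) {
  rows <- prepared %>%
    filter(.data$participant_id %in% participants,
           .data$surface == "treadmill", .data$channel == !!channel) %>%
    arrange(.data$participant_id, .data$speed)
  missing <- setdiff(participants, unique(rows$participant_id))
  if (length(missing)) {
    stop_data("no treadmill sessions prepared for participant(s) %s",
              paste(missing, collapse = ", "))
  }
  bind_frame_sets(purrr::map(seq_len(nrow(rows)), function(i) {
    make_frames(rows$reg_seg[[i]], rows$kin_seg[[i]], joint)
  }))
}

test_frames <- function(prepared, participant, channel, joint) {
  row <- prepared %>%
    filter(.data$participant_id == !!participant,
           .data$surface == "level_ground", .data$channel == !!channel)
  if (nrow(row) != 1) {
    stop_data("no level-ground session prepared for participant %s",
              participant)
  }
  list(frames = make_frames(row$reg_seg[[1]], row$kin_seg[[1]], joint),
       kin_seg = row$kin_seg[[1]])
}

evaluate_fold <- function(prepared, train_ids, test_id, channel, joint,
                          config, scheme) {
  train <- training_frames(prepared, train_ids, channel, joint)
  test <- test_frames(prepared, test_id, channel, joint)
  cfg <- cnn_config(
    epochs = config$epochs, batch_size = config$batch_size,
    rng_seed = child_seed(config$master_seed, scheme, test_id, channel, joint)
  )
  fit <- fit_cnn(train, cfg)
  pred <- predict(fit, test$frames)
  metrics <- angle_metrics(test$kin_seg, pred, joint)
  bind_cols(
    tibble(scheme = scheme, participant_id = test_id,
           channel = channel, n_train_frames = n_frames(train)),
    metrics
  )
}

run_scheme <- function(prepared, ids, config, scheme) {
  grid <- tidyr::expand_grid(participant_id = ids,
                             joint = config$joints,
                             channel = config$channels)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    test_id <- grid$participant_id[i]
    train_ids <- if (scheme == "intra") test_id else setdiff(ids, test_id)
    evaluate_fold(prepared, train_ids, test_id, grid$channel[i],
                  grid$joint[i], config, scheme)
  })
}

#' Run a complete prediction study on a synthetic cohort
#'
#' Simulates the cohort and its sessions, prepares all frames, trains
#' one network per (scheme x joint x channel x fold) and evaluates each
#' on the held-out level-ground segment, then compares the two
#' regressor channels with paired t-tests.
#'
#' @param config A [study_config()].
#' @return A `study_result`: list with `metrics` (one row per scheme x
#'   joint x channel x participant), `comparisons` (one row per scheme
#'   x joint x parameter), `cohort`, `config` and provenance.
#' @export
run_study <- function(config = study_config()) {
  cohort <- make_cohort(config$n_participants, config$master_seed)
  sessions <- simulate_study(
    cohort, seed = child_seed(config$master_seed, "sessions"),
    session_duration = config$session_duration,
    treadmill_model = config$treadmill_model,
    level_model = config$level_model
  )
  plan <- segmentation_plan(config$session_duration)
  prepared <- prepare_study(sessions, config$channels, plan)
  ids <- cohort$participant_id
  metrics <- bind_rows(lapply(config$schemes, function(s) {
    run_scheme(prepared, ids, config, s)
  }))
  comparisons <- if (length(config$channels) == 2) {
    compare_channels(metrics)
  } else {
    tibble()
  }
  structure(
    list(metrics = metrics, comparisons = comparisons, cohort = cohort,
         config = config,
         provenance = list(
           master_seed = config$master_seed,
           n_sessions = nrow(sessions),
           package_version = as.character(utils::packageVersion("gaitcnn")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
         )),
    class = "study_result"
  )
}

#' Run only the intraparticipant scheme
#'
#' Trains on each participant's own treadmill frames (four speeds
#' concatenated in ascending order) and tests on that participant's
#' level-ground segment.
#'
#' @param config A [study_config()].
#' @return A `study_result` restricted to the intra scheme.
#' @export
run_intra <- function(config = study_config()) {
  config$schemes <- "intra"
  run_study(config)
}

#' Run only the leave-one-participant-out scheme
#'
#' Fold k trains on the treadmill frames of all participants except k
#' and tests on participant k's level-ground segment; with n
#' participants there are exactly n folds.
#'
#' @param config A [study_config()].
#' @return A `study_result` restricted to the inter scheme.
#' @export
run_inter <- function(config = study_config()) {
  config$schemes <- "inter"
  run_study(config)
}

#' Paired accelerometer-vs-gyroscope comparison tables
#'
#' For every scheme x joint, compares R2, RMSE, NRMSE, STD and NSTD
#' between the two channels across participants with two-tailed paired
#' t-tests (ROM, a property of the measured trace, is reported but not
#' tested). Degenerate rows (zero-variance differences) are surfaced in
#' the `note` column rather than aborting the table.
#'
#' @param metrics The `metrics` tibble of a `study_result` (both
#'   channels present for every participant).
#' @return A tibble with one row per scheme x joint x parameter.
#' @export
compare_channels <- function(metrics) {
  params <- c("r2", "rmse", "nrmse", "std", "nstd")
  groups <- metrics %>%
    dplyr::distinct(.data$scheme, .data$joint)
  purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    sub <- metrics %>%
      filter(.data$scheme == groups$scheme[g], .data$joint == groups$joint[g])
    if (nrow(sub) != 2 * length(unique(sub$participant_id))) {
      bad <- names(which(table(sub$participant_id) != 2))
      stop_data("unpaired metrics for participant(s) %s",
                paste(bad, collapse = ", "))
    }
    wide <- sub %>%
      select(all_of(c("participant_id", "channel", params))) %>%
      tidyr::pivot_wider(names_from = "channel",
                         values_from = all_of(params))
    purrr::map_dfr(params, function(p) {
      accel <- wide[[paste0(p, "_accel_y")]]
      gyro <- wide[[paste0(p, "_gyro_resultant_xz")]]
      # folds whose traces yielded no matched peaks carry NA peak
      # metrics; the paired test uses the complete pairs only
      ok <- stats::complete.cases(accel, gyro)
      row <- tryCatch({
        if (sum(ok) < 2) {
          stop_metric("fewer than 2 complete participant pairs")
        }
        mutate(paired_comparison(accel[ok], gyro[ok], p),
               n_pairs = sum(ok), note = NA_character_)
      },
      gaitcnn_metric_error = function(e) {
        tibble(parameter = p,
               mean_accel = mean(accel[ok]), sd_accel = sd(accel[ok]),
               mean_gyro = mean(gyro[ok]), sd_gyro = sd(gyro[ok]),
               t_statistic = NA_real_, df = NA_real_,
               p_value = NA_real_, significant = NA,
               schober_accel = NA_character_,
               schober_gyro = NA_character_,
               n_pairs = sum(ok), note = conditionMessage(e))
      })
      bind_cols(tibble(scheme = groups$scheme[g], joint = groups$joint[g]),
                row)
    })
  })
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "<study_result> %d participants | schemes: %s | %d metric rows\n",
    x$config$n_participants, paste(x$config$schemes, collapse = ", "),
    nrow(x$metrics)
  ))
  print(glance(x))
  invisible(x)
}

#' Per-fold metrics of a study
#'
#' @param x A `study_result`.
#' @param ... Unused.
#' @return The metrics tibble (one row per scheme x joint x channel x
#'   participant).
#' @exportS3Method
tidy.study_result <- function(x, ...) x$metrics

#' Group-level summary of a study
#'
#' @param x A `study_result`.
#' @param ... Unused.
#' @return A tibble of mean (SD) metrics per scheme x joint x channel.
#' @exportS3Method
glance.study_result <- function(x, ...) {
  x$metrics %>%
    group_by(.data$scheme, .data$joint, .data$channel) %>%
    summarise(
      n = n(),
      mean_r2 = mean(.data$r2), sd_r2 = sd(.data$r2),
      mean_rmse = mean(.data$rmse), mean_nrmse = mean(.data$nrmse),
      mean_std = mean(.data$std), mean_nstd = mean(.data$nstd),
      mean_rom = mean(.data$rom),
      .groups = "drop"
    )
}

#' Plot the per-fold metric distributions of a study
#'
#' @param object A `study_result`.
#' @param metric Which metric column to plot (default `"r2"`).
#' @param ... Unused.
#' @return A ggplot: one panel per scheme, channels side by side per
#'   joint.
#' @exportS3Method
autoplot.study_result <- function(object, metric = "r2", ...) {
  ggplot2::ggplot(
    object$metrics,
    ggplot2::aes(x = .data$joint, y = .data[[metric]],
                 fill = .data$channel)
  ) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay an actual angle segment with its prediction
#'
#' @param actual A kinematics segment (tibble with `t` and the joint
#'   column).
#' @param predicted A prediction tibble (`center_time`, `.pred`).
#' @param joint `"knee"` or `"hip"`.
#' @return A ggplot of the two traces against time.
#' @export
plot_prediction <- function(actual, predicted, joint = c("knee", "hip")) {
  joint <- match.arg(joint)
  df <- bind_rows(
    tibble(t = actual$t, angle = actual[[joint]], trace = "actual"),
    tibble(t = predicted$center_time, angle = predicted$.pred,
           trace = "predicted")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$angle,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = sprintf("%s flexion (deg)", joint)) +
    ggplot2::theme_minimal()
}
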
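#' Simulate the hand choice of a temporal-order judgment
#'
#' Logistic choice model: the correct (first-stimulated) hand is chosen with
#' probability `plogis(beta0 + beta_soa * soa - beta_cross * crossed)`.
#' Longer SOAs make the order easier to judge; a crossed posture at the time
#' of stimulation penalizes performance, reproducing the classic crossing
#' effect. The model is deliberately descriptive: the pipeline only needs
#' realistic proportions of correct and incorrect trials.
#'
#' @param first_hand Character vector, `"left"` or `"right"`: which hand was
#'   stimulated first.
#' @param crossed Logical vector: were the hands crossed at the time of the
#'   first stimulus?
#' @param soa Stimulus onset asynchrony in ms (> 0).
#' @param params Named vector with `beta0`, `beta_soa`, `beta_cross`.
#' @return Character vector of chosen response hands.
#' @export
choose_response_hand <- function(first_hand, crossed, soa,
                                 params = c(beta0 = 0.3, beta_soa = 0.01,
                                            beta_cross = 1.0)) {
  stopifnot(all(soa > 0), all(first_hand %in% c("left", "right")))
  p <- plogis(params[["beta0"]] + params[["beta_soa"]] * soa -
                params[["beta_cross"]] * as.numeric(crossed))
  correct <- runif(length(first_hand)) < p
  other <- ifelse(first_hand == "left", "right", "left")
  ifelse(correct, first_hand, other)
}

## evaluate a hand's planar position at times t from per-trial geometry vectors
.hand_pos <- function(t, onset, duration, sx, sy, ex, ey) {
  h <- min_jerk_shape((t - onset) / duration)
  cbind(x = sx + h * (ex - sx), y = sy + h * (ey - sy))
}

#' Generate localization reports under a generative hypothesis
#'
#' Produces the reported (x, y) location for each trial given the chosen
#' response hand. All three accounts share the temporal-uncertainty
#' machinery: a perceived stimulus time `t_hat = t_ref + temporal_bias +
#' N(0, temporal_noise_sd)` is combined with a hand's trajectory (clamped to
#' the start/end points outside the movement), plus isotropic spatial noise.
#' They differ in which time and which hand anchor the report on
#' incorrect-choice trials:
#' * `time_reconstruction`: chosen hand at the *first* stimulus time;
#' * `stimulus_switch`: chosen hand at its own (second) stimulus time;
#' * `space_to_limb`: the *correct* hand's location at the first stimulus
#'   time (the report is executed by the chosen, incorrect hand but lands on
#'   the correct hand's path).
#'
#' @param trials A trial tibble as built by [generate_dataset()] (needs the
#'   stimulus times, response hand and per-hand trajectory annotations).
#' @param hypothesis One of `"time_reconstruction"`, `"stimulus_switch"`,
#'   `"space_to_limb"`.
#' @param temporal_noise_sd,temporal_bias,spatial_noise_sd Noise parameters
#'   (ms, ms, mm).
#' @return A two-column matrix of reported positions (mm).
#' @export
generate_localization <- function(trials, hypothesis,
                                  temporal_noise_sd = 90, temporal_bias = 0,
                                  spatial_noise_sd = 6) {
  if (!hypothesis %in% c("time_reconstruction", "stimulus_switch",
                         "space_to_limb")) {
    stop_tojshift(paste0("unknown hypothesis: ", hypothesis),
                  "tojshift_config_error")
  }
  n <- nrow(trials)
  correct <- trials$response_hand == trials$first_hand
  aim_time <- switch(hypothesis,
    time_reconstruction = trials$t1_ms,
    stimulus_switch = ifelse(correct, trials$t1_ms, trials$t2_ms),
    space_to_limb = trials$t1_ms)
  ## which hand's trajectory anchors the report
  anchor <- trials$response_hand
  if (hypothesis == "space_to_limb") {
    anchor <- ifelse(correct, trials$response_hand, trials$first_hand)
  }
  t_hat <- aim_time + temporal_bias + rnorm(n, 0, temporal_noise_sd)
  left <- anchor == "left"
  pick <- function(col_l, col_r) ifelse(left, trials[[col_l]], trials[[col_r]])
  pos <- .hand_pos(t_hat,
                   pick("onset_left_ms", "onset_right_ms"),
                   pick("duration_left_ms", "duration_right_ms"),
                   pick("start_x_left_mm", "start_x_right_mm"),
                   pick("start_y_left_mm", "start_y_right_mm"),
                   pick("end_x_left_mm", "end_x_right_mm"),
                   pick("end_y_left_mm", "end_y_right_mm"))
  pos + matrix(rnorm(2 * n, 0, spatial_noise_sd), ncol = 2)
}

#' Generate a complete synthetic experiment
#'
#' Simulates every trial of the design in `config`: bimanual minimum-jerk
#' reach kinematics, a stimulus pair separated by the trial's SOA with the
#' first-stimulated hand balanced within each cell, a hand choice from the
#' logistic TOJ model, and a localization report generated under the
#' configured hypothesis. Generation is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param include_trajectories If `TRUE`, also render sampled marker tables
#'   (with the configured marker noise and drop-outs) for every trial; for
#'   large simulation studies this is the expensive part and can be skipped,
#'   since trials carry their ground-truth kinematic annotations.
#' @return A list with `trials` (one row per trial) and `trajectories`
#'   (a tibble, or `NULL`), plus the config as attribute `"config"`.
#' @examples
#' cfg <- sim_config(n_participants = 2, trials_per_condition = 10)
#' dat <- generate_dataset(cfg, include_trajectories = FALSE)
#' nrow(dat$trials)  # 2 participants x 4 conditions x 1 SOA x 10 trials = 80
#' @export
generate_dataset <- function(config, include_trajectories = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  lat <- config$lateral_offset
  start_y <- 100 + config$movement_distance
  end_y <- 100
  design <- merge(config$conditions,
                  data.frame(soa_ms = config$soa_values))
  n_cell <- config$trials_per_condition

  ## participant-level variation
  p_ids <- sprintf("P%02d", seq_len(config$n_participants))
  p_dur <- config$movement_duration_mean +
    rnorm(config$n_participants, 0, config$participant_sd[["duration"]])
  p_b0 <- config$toj_choice_params[["beta0"]] +
    rnorm(config$n_participants, 0, config$participant_sd[["beta0"]])

  blocks <- vector("list", config$n_participants * nrow(design))
  k <- 0
  for (p in seq_len(config$n_participants)) {
    for (d in seq_len(nrow(design))) {
      k <- k + 1
      sp <- design$start_posture[d]
      ep <- design$end_posture[d]
      ## lateral sign of the LEFT hand at start/end (+ = right of midline)
      sxl <- if (sp == "crossed") lat else -lat
      exl <- if (ep == "crossed") lat else -lat
      ## balanced first-stimulated hand, pseudo-random order
      first_hand <- sample(rep(c("left", "right"), length.out = n_cell))
      latency <- pmax(rnorm(n_cell, config$onset_latency_mean,
                            config$onset_latency_sd), 0)
      dur <- pmin(pmax(rnorm(n_cell, p_dur[p], config$movement_duration_sd),
                       210), 990)
      jit <- function() rnorm(n_cell, 0, config$hand_jitter_sd)
      onset_l <- pmax(latency + jit(), 0)
      onset_r <- pmax(latency + jit(), 0)
      dur_l <- pmin(pmax(dur + jit(), 210), 990)
      dur_r <- pmin(pmax(dur + jit(), 210), 990)
      t1 <- runif(n_cell, config$stim_window[1], config$stim_window[2])
      t2 <- t1 + design$soa_ms[d]

      blocks[[k]] <- tibble(
        participant_id = p_ids[p],
        start_posture = sp, end_posture = ep,
        soa_ms = design$soa_ms[d],
        first_hand = first_hand, t1_ms = t1, t2_ms = t2,
        onset_left_ms = onset_l, duration_left_ms = dur_l,
        offset_left_ms = onset_l + dur_l,
        onset_right_ms = onset_r, duration_right_ms = dur_r,
        offset_right_ms = onset_r + dur_r,
        start_x_left_mm = sxl, start_y_left_mm = start_y,
        end_x_left_mm = exl, end_y_left_mm = end_y,
        start_x_right_mm = -sxl, start_y_right_mm = start_y,
        end_x_right_mm = -exl, end_y_right_mm = end_y,
        beta0_p = p_b0[p]
      )
    }
  }
  trials <- bind_rows(blocks)
  trials$trial_id <- sprintf("%s_T%05d", trials$participant_id,
                             stats::ave(seq_len(nrow(trials)),
                                        trials$participant_id,
                                        FUN = seq_along))

  ## posture at the first stimulus: lateral positions of the two hands at t1
  xl <- .hand_pos(trials$t1_ms, trials$onset_left_ms, trials$duration_left_ms,
                  trials$start_x_left_mm, trials$start_y_left_mm,
                  trials$end_x_left_mm, trials$end_y_left_mm)[, 1]
  xr <- .hand_pos(trials$t1_ms, trials$onset_right_ms,
                  trials$duration_right_ms,
                  trials$start_x_right_mm, trials$start_y_right_mm,
                  trials$end_x_right_mm, trials$end_y_right_mm)[, 1]
  trials$crossed_at_t1 <- xl > xr

  ## ground-truth postural change (lateral crossing) for posture-change trials
  trials$postural_change_ms <- NA_real_
  chg <- trials$start_posture != trials$end_posture
  if (any(chg)) {
    idx <- which(chg)
    trials$postural_change_ms[idx] <- vapply(idx, function(i) {
      f <- function(t) {
        (trials$start_x_left_mm[i] +
           min_jerk_shape((t - trials$onset_left_ms[i]) /
                            trials$duration_left_ms[i]) *
           (trials$end_x_left_mm[i] - trials$start_x_left_mm[i])) -
          (trials$start_x_right_mm[i] +
             min_jerk_shape((t - trials$onset_right_ms[i]) /
                              trials$duration_right_ms[i]) *
             (trials$end_x_right_mm[i] - trials$start_x_right_mm[i]))
      }
      lo <- min(trials$onset_left_ms[i], trials$onset_right_ms[i])
      hi <- max(trials$offset_left_ms[i], trials$offset_right_ms[i])
      uniroot(f, c(lo, hi))$root
    }, 0)
  }

  ## TOJ hand choice and localization report
  pr <- config$toj_choice_params
  p_correct <- plogis(trials$beta0_p + pr[["beta_soa"]] * trials$soa_ms -
                        pr[["beta_cross"]] * as.numeric(trials$crossed_at_t1))
  is_correct <- runif(nrow(trials)) < p_correct
  other <- ifelse(trials$first_hand == "left", "right", "left")
  trials$response_hand <- ifelse(is_correct, trials$first_hand, other)
  trials$beta0_p <- NULL

  rep_pos <- generate_localization(trials, config$hypothesis,
                                   config$temporal_noise_sd,
                                   config$temporal_bias,
                                   config$spatial_noise_sd)
  trials$reported_x_mm <- rep_pos[, 1]
  trials$reported_y_mm <- rep_pos[, 2]
  trials$hypothesis <- config$hypothesis

  core <- c("trial_id", "participant_id", "start_posture", "end_posture",
            "soa_ms", "first_hand", "t1_ms", "t2_ms", "response_hand",
            "reported_x_mm", "reported_y_mm")
  trials <- trials[, c(core, setdiff(names(trials), core))]

  trajectories <- NULL
  if (include_trajectories) {
    trajectories <- render_trajectories(trials, config)
  }
  out <- list(trials = trials, trajectories = trajectories)
  attr(out, "config") <- config
  out
}

#' Render sampled marker tables for simulated trials
#'
#' Converts the analytic per-trial kinematic annotations into tidy sampled
#' trajectories at the configured sampling rate, with marker noise and
#' optional gaps.
#'
#' @param trials A trial tibble from [generate_dataset()].
#' @param config The originating [sim_config()].
#' @return A tibble with columns `trial_id`, `hand`, `t_ms`, `x_mm`, `y_mm`.
#' @export
render_trajectories <- function(trials, config) {
  step <- 1000 / config$sampling_rate
  per_hand <- function(hand) {
    pre <- if (hand == "left") "left" else "right"
    onset <- trials[[paste0("onset_", pre, "_ms")]]
    dur <- trials[[paste0("duration_", pre, "_ms")]]
    t_end <- onset + dur + 200
    ns <- floor(t_end / step) + 1
    idx <- rep(seq_len(nrow(trials)), ns)
    ts <- unlist(lapply(ns, function(n) seq(0, by = step, length.out = n)))
    pos <- .hand_pos(ts, onset[idx], dur[idx],
                     trials[[paste0("start_x_", pre, "_mm")]][idx],
                     trials[[paste0("start_y_", pre, "_mm")]][idx],
                     trials[[paste0("end_x_", pre, "_mm")]][idx],
                     trials[[paste0("end_y_", pre, "_mm")]][idx])
    if (config$traj_noise_sd > 0) {
      pos <- pos + matrix(rnorm(length(pos), 0, config$traj_noise_sd),
                          ncol = 2)
    }
    if (config$gap_prob > 0) {
      gap <- runif(length(ts)) < config$gap_prob
      pos[gap, ] <- NA_real_
    }
    tibble(trial_id = trials$trial_id[idx], hand = hand, t_ms = ts,
           x_mm = pos[, 1], y_mm = pos[, 2])
  }
  bind_rows(per_hand("left"), per_hand("right")) %>%
    arrange(.data$trial_id, .data$hand, .data$t_ms)
}
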
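#' Simulation configuration
#'
#' Bundles every parameter of the synthetic experiment generator. Defaults
#' reproduce the two-stimulus task design: ~300 mm reaches toward the body,
#' stimulus pairs delivered 50-800 ms after the movement cue (uniform), and
#' a logistic hand-choice model whose defaults yield upwards of 15% wrong-hand
#' reports even with uncrossed hands at a 110-ms stimulus onset asynchrony,
#' with substantially more errors while the arms are crossed.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_condition Trials per participant, condition and SOA.
#' @param conditions Data frame with columns `start_posture`, `end_posture`
#'   (each `"uncrossed"` or `"crossed"`), one row per movement condition.
#'   Defaults to all four combinations.
#' @param soa_values Stimulus onset asynchronies in ms (all > 0).
#' @param hypothesis Generative account used for localization reports: one of
#'   `"time_reconstruction"`, `"stimulus_switch"`, `"space_to_limb"`.
#' @param movement_distance Reach extent along the movement axis, mm.
#' @param movement_duration_mean,movement_duration_sd Movement duration
#'   distribution, ms; draws are truncated to (210, 990) so simulated trials
#'   lie inside the 200-1000 ms duration-exclusion window.
#' @param onset_latency_mean,onset_latency_sd Movement onset latency after
#'   the cue, ms (truncated at 0).
#' @param hand_jitter_sd Per-hand jitter of onset and duration, ms; keeps the
#'   two hands near-synchronous.
#' @param stim_window Length-2 vector, (min, max) ms after the cue from which
#'   the first stimulus time is drawn uniformly.
#' @param temporal_noise_sd Standard deviation of the perceived stimulus
#'   time, ms (the temporal-uncertainty width).
#' @param temporal_bias Mean shift of the perceived stimulus time, ms.
#' @param spatial_noise_sd Isotropic spatial noise of the pointing report, mm.
#' @param toj_choice_params Named numeric vector `c(beta0, beta_soa,
#'   beta_cross)`: the probability of choosing the correct (first-stimulated)
#'   hand is `plogis(beta0 + beta_soa * soa - beta_cross * crossed)`, where
#'   `crossed` indicates the hands were crossed at the first stimulus time.
#' @param participant_sd Between-participant standard deviations, a named
#'   numeric vector with entries `duration` (ms) and `beta0` (log-odds).
#' @param lateral_offset Unsigned lateral distance of each hand from the body
#'   midline, mm.
#' @param sampling_rate Marker sampling rate for rendered trajectories, Hz.
#' @param traj_noise_sd Marker noise for rendered trajectories, mm.
#' @param gap_prob Per-sample marker drop-out probability.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_dataset()], [exp1_config()], [exp2_config()]
#' @export
sim_config <- function(n_participants = 12,
                       trials_per_condition = 300,
                       conditions = NULL,
                       soa_values = 110,
                       hypothesis = c("time_reconstruction",
                                      "stimulus_switch",
                                      "space_to_limb"),
                       movement_distance = 300,
                       movement_duration_mean = 500,
                       movement_duration_sd = 80,
                       onset_latency_mean = 250,
                       onset_latency_sd = 50,
                       hand_jitter_sd = 10,
                       stim_window = c(50, 800),
                       temporal_noise_sd = 90,
                       temporal_bias = 0,
                       spatial_noise_sd = 6,
                       toj_choice_params = c(beta0 = 0.3,
                                             beta_soa = 0.01,
                                             beta_cross = 1.0),
                       participant_sd = c(duration = 30, beta0 = 0.2),
                       lateral_offset = 100,
                       sampling_rate = 250,
                       traj_noise_sd = 0.2,
                       gap_prob = 0,
                       seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(conditions)) {
    conditions <- expand.grid(start_posture = c("uncrossed", "crossed"),
                              end_posture = c("uncrossed", "crossed"),
                              stringsAsFactors = FALSE)
  }
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  if (nrow(conditions) == 0) {
    stop_tojshift("conditions must contain at least one row",
                  "tojshift_config_error")
  }
  if (!all(c("start_posture", "end_posture") %in% names(conditions)) ||
      !all(unlist(conditions[c("start_posture", "end_posture")]) %in%
             c("uncrossed", "crossed"))) {
    stop_tojshift(
      "conditions must have start_posture/end_posture in {uncrossed, crossed}",
      "tojshift_config_error")
  }
  if (any(soa_values <= 0)) {
    stop_tojshift("all SOA values must be positive", "tojshift_config_error")
  }
  if (length(stim_window) != 2 || stim_window[1] >= stim_window[2]) {
    stop_tojshift("stim_window must be (min, max) with min < max",
                  "tojshift_config_error")
  }
  sds <- c(movement_duration_sd, onset_latency_sd, hand_jitter_sd,
           temporal_noise_sd, spatial_noise_sd, traj_noise_sd)
  if (any(sds < 0)) {
    stop_tojshift("standard deviations must be non-negative",
                  "tojshift_config_error")
  }
  if (movement_duration_mean <= 200 || movement_duration_mean >= 1000) {
    stop_tojshift("movement_duration_mean must lie in (200, 1000) ms",
                  "tojshift_config_error")
  }
  stopifnot(all(c("beta0", "beta_soa", "beta_cross") %in%
                  names(toj_choice_params)))
  structure(
    list(n_participants = as.integer(n_participants),
         trials_per_condition = as.integer(trials_per_condition),
         conditions = conditions,
         soa_values = as.numeric(soa_values),
         hypothesis = hypothesis,
         movement_distance = movement_distance,
         movement_duration_mean = movement_duration_mean,
         movement_duration_sd = movement_duration_sd,
         onset_latency_mean = onset_latency_mean,
         onset_latency_sd = onset_latency_sd,
         hand_jitter_sd = hand_jitter_sd,
         stim_window = as.numeric(stim_window),
         temporal_noise_sd = temporal_noise_sd,
         temporal_bias = temporal_bias,
         spatial_noise_sd = spatial_noise_sd,
         toj_choice_params = toj_choice_params,
         participant_sd = participant_sd,
         lateral_offset = lateral_offset,
         sampling_rate = sampling_rate,
         traj_noise_sd = traj_noise_sd,
         gap_prob = gap_prob,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Canned experiment designs
#'
#' `exp1_config()` is the four-posture single-SOA design (all combinations of
#' uncrossed/crossed start and end postures, SOA 110 ms).
#' `exp2_config()` is the two-posture SOA-sweep design (uncrossed-uncrossed
#' and crossed-crossed, SOAs 60/85/110/135 ms).
#'
#' @param n_participants,trials_per_condition,seed,... Passed to
#'   [sim_config()].
#' @return A `sim_config`.
#' @export
exp1_config <- function(n_participants = 12, trials_per_condition = 300,
                        seed = 1L, ...) {
  sim_config(n_participants = n_participants,
             trials_per_condition = trials_per_condition,
             soa_values = 110, seed = seed, ...)
}

#' @rdname exp1_config
#' @export
exp2_config <- function(n_participants = 18, trials_per_condition = 224,
                        seed = 1L, ...) {
  sim_config(n_participants = n_participants,
             trials_per_condition = trials_per_condition,
             conditions = data.frame(
               start_posture = c("uncrossed", "crossed"),
               end_posture = c("uncrossed", "crossed")),
             soa_values = c(60, 85, 110, 135),
             seed = seed, ...)
}

## flat key=value serialization so a run's generator settings travel with it
#' Write / read a simulation config as a flat key-value file
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  conds <- paste(config$conditions$start_posture,
                 config$conditions$end_posture, sep = ":", collapse = ",")
  kv <- c(
    n_participants = config$n_participants,
    trials_per_condition = config$trials_per_condition,
    conditions = conds,
    soa_values = paste(config$soa_values, collapse = ","),
    hypothesis = config$hypothesis,
    movement_distance = config$movement_distance,
    movement_duration_mean = config$movement_duration_mean,
    movement_duration_sd = config$movement_duration_sd,
    onset_latency_mean = config$onset_latency_mean,
    onset_latency_sd = config$onset_latency_sd,
    hand_jitter_sd = config$hand_jitter_sd,
    stim_window_min = config$stim_window[1],
    stim_window_max = config$stim_window[2],
    temporal_noise_sd = config$temporal_noise_sd,
    temporal_bias = config$temporal_bias,
    spatial_noise_sd = config$spatial_noise_sd,
    beta0 = config$toj_choice_params[["beta0"]],
    beta_soa = config$toj_choice_params[["beta_soa"]],
    beta_cross = config$toj_choice_params[["beta_cross"]],
    participant_sd_duration = config$participant_sd[["duration"]],
    participant_sd_beta0 = config$participant_sd[["beta0"]],
    lateral_offset = config$lateral_offset,
    sampling_rate = config$sampling_rate,
    traj_noise_sd = config$traj_noise_sd,
    gap_prob = config$gap_prob,
    seed = config$seed
  )
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                   vapply(kv, `[[`, "", 1))
  conds <- do.call(rbind, strsplit(strsplit(vals[["conditions"]], ",")[[1]],
                                   ":", fixed = TRUE))
  num <- function(key) as.numeric(vals[[key]])
  sim_config(
    n_participants = num("n_participants"),
    trials_per_condition = num("trials_per_condition"),
    conditions = data.frame(start_posture = conds[, 1],
                            end_posture = conds[, 2]),
    soa_values = as.numeric(strsplit(vals[["soa_values"]], ",")[[1]]),
    hypothesis = vals[["hypothesis"]],
    movement_distance = num("movement_distance"),
    movement_duration_mean = num("movement_duration_mean"),
    movement_duration_sd = num("movement_duration_sd"),
    onset_latency_mean = num("onset_latency_mean"),
    onset_latency_sd = num("onset_latency_sd"),
    hand_jitter_sd = num("hand_jitter_sd"),
    stim_window = c(num("stim_window_min"), num("stim_window_max")),
    temporal_noise_sd = num("temporal_noise_sd"),
    temporal_bias = num("temporal_bias"),
    spatial_noise_sd = num("spatial_noise_sd"),
    toj_choice_params = c(beta0 = num("beta0"), beta_soa = num("beta_soa"),
                          beta_cross = num("beta_cross")),
    participant_sd = c(duration = num("participant_sd_duration"),
                       beta0 = num("participant_sd_beta0")),
    lateral_offset = num("lateral_offset"),
    sampling_rate = num("sampling_rate"),
    traj_noise_sd = num("traj_noise_sd"),
    gap_prob = num("gap_prob"),
    seed = num("seed")
  )
}
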
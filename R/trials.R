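#' Score temporal-order judgments
#'
#' A TOJ is correct when the hand used for the localization response is the
#' hand that was stimulated first.
#'
#' @param trials Trial tibble with `first_hand` and `response_hand`.
#' @return Logical vector, one element per trial.
#' @export
score_toj <- function(trials) {
  stopifnot(all(trials$response_hand %in% c("left", "right")))
  trials$response_hand == trials$first_hand
}

#' Assign each trial to a movement phase
#'
#' Phases partition the stimulus timeline into `before_movement`,
#' `during_start_posture`, `during_end_posture` and `after_movement`, based
#' on the first stimulus time `t1` relative to the bimanual movement
#' interval (the mean of the two hands' onsets and offsets). Within the
#' movement, trials of conditions without a postural change are split at the
#' temporal midpoint; trials of conditions with a postural change are split
#' at the postural-change time. Boundary ties resolve to the later phase.
#'
#' @param trials Trial tibble with stimulus times, per-hand onset/offset
#'   annotations and `postural_change_ms` where the posture changes.
#' @return Factor with the four phase levels.
#' @export
assign_phase <- function(trials) {
  onset <- (trials$onset_left_ms + trials$onset_right_ms) / 2
  offset <- (trials$offset_left_ms + trials$offset_right_ms) / 2
  change <- trials$start_posture != trials$end_posture
  if (any(change & !is.finite(trials$postural_change_ms))) {
    stop_tojshift(
      "posture-change trial without a postural_change_ms annotation",
      "tojshift_unphaseable")
  }
  split_at <- ifelse(change, trials$postural_change_ms, (onset + offset) / 2)
  t1 <- trials$t1_ms
  phase <- ifelse(t1 < onset, "before_movement",
           ifelse(t1 > offset, "after_movement",
           ifelse(t1 < split_at, "during_start_posture",
                  "during_end_posture")))
  factor(phase, levels = c("before_movement", "during_start_posture",
                           "during_end_posture", "after_movement"))
}

## Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

#' Summarize TOJ accuracy by condition and movement phase
#'
#' Tabulates the proportion of correct hand assignments with Wilson binomial
#' confidence intervals, per participant and pooled across participants, for
#' every combination of movement condition and phase. Empty cells are kept
#' with `n = 0` and an undefined proportion. The output is tidy and suitable
#' for external mixed-model analysis.
#'
#' @param trials Trial tibble (valid trials only are summarized if a `valid`
#'   column is present).
#' @param by_soa Also split cells by SOA (for multi-SOA designs).
#' @return A tibble with columns `level` (`"participant"` or `"pooled"`),
#'   `participant_id`, condition columns, `phase`, `n`, `k`, `prop_correct`,
#'   `ci_lo`, `ci_hi`.
#' @export
summarize_toj <- function(trials, by_soa = length(unique(trials$soa_ms)) > 1) {
  if ("valid" %in% names(trials)) trials <- trials[trials$valid, ]
  trials$correct <- score_toj(trials)
  trials$phase <- assign_phase(trials)
  keys <- c("start_posture", "end_posture", if (by_soa) "soa_ms", "phase")

  cell_stats <- function(df, level, pid) {
    grid <- expand.grid(c(
      lapply(df[setdiff(keys, "phase")], function(x) sort(unique(x))),
      list(phase = levels(df$phase))), stringsAsFactors = FALSE)
    counts <- df %>%
      group_by(dplyr::across(dplyr::all_of(keys))) %>%
      summarise(n = dplyr::n(), k = sum(.data$correct), .groups = "drop")
    out <- left_join(as_tibble(grid), counts, by = keys)
    out$n[is.na(out$n)] <- 0L
    out$k[is.na(out$k)] <- 0L
    ci <- t(mapply(wilson_ci, out$k, out$n))
    out$prop_correct <- ifelse(out$n > 0, out$k / out$n, NA_real_)
    out$ci_lo <- ci[, 1]
    out$ci_hi <- ci[, 2]
    out$level <- level
    out$participant_id <- pid
    out
  }

  per_p <- bind_rows(lapply(split(trials, trials$participant_id), function(d) {
    cell_stats(d, "participant", d$participant_id[1])
  }))
  pooled <- cell_stats(trials, "pooled", NA_character_)
  out <- bind_rows(per_p, pooled)
  out[, c("level", "participant_id", keys, "n", "k", "prop_correct",
          "ci_lo", "ci_hi")]
}
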
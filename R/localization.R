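#' Movement axis of a reach
#'
#' The movement axis is the straight line from the hand's position at
#' movement onset to its position at movement offset. Localization errors
#' are signed projections onto this axis, positive in movement direction.
#'
#' @param start_point,end_point Numeric (x, y) positions, mm.
#' @return A list with `origin` (the start point) and `direction` (unit
#'   vector).
#' @examples
#' movement_axis(c(0, 0), c(300, 400))$direction  # c(0.6, 0.8)
#' @export
movement_axis <- function(start_point, end_point) {
  d <- as.numeric(end_point) - as.numeric(start_point)
  len <- sqrt(sum(d^2))
  if (len == 0) {
    stop_tojshift("onset and offset positions coincide",
                  "tojshift_degenerate_axis")
  }
  list(origin = as.numeric(start_point), direction = d / len)
}

#' Signed localization error of a single report
#'
#' The difference between the reported location and the hand's true position
#' at the reference time, projected onto the movement axis; positive values
#' are errors in movement direction (toward the end position).
#'
#' @param reported Numeric (x, y), the reported location, mm.
#' @param true_position Numeric (x, y), the hand position at the referenced
#'   stimulus time, mm.
#' @param axis A [movement_axis()].
#' @return Signed error in mm.
#' @export
localization_error <- function(reported, true_position, axis) {
  sum((as.numeric(reported) - as.numeric(true_position)) * axis$direction)
}

#' Build localization samples from a trial table
#'
#' For every (valid) trial, projects the reported location and the reporting
#' hand's true position at the referenced stimulus time onto that hand's
#' movement axis, yielding one `(t, error)` sample. The time coordinate `t`
#' is always the *first* stimulus time relative to the reporting hand's
#' movement onset; `reference` selects which stimulus time anchors the true
#' position used for the error (`"time1"`, or `"time2"` for the hypothetical
#' template built from correct trials). With `reference = "time2"` the true
#' position lies further along the path, so the resulting curve is displaced
#' leftward/downward relative to the time-1 curve.
#'
#' Samples carry the reporting hand's kinematic annotations (`path_mm`,
#' `duration_ms`, `rep_proj`) so that the time-shift machinery can re-derive
#' errors against displaced reference times.
#'
#' @param trials Trial tibble with per-hand kinematic annotations (from
#'   [generate_dataset()] or [preprocess_trajectories()]).
#' @param reference `"time1"` or `"time2"`.
#' @param subset `"all"`, `"correct"` or `"incorrect"` TOJ trials.
#' @return A tibble of localization samples.
#' @export
localization_samples <- function(trials,
                                 reference = c("time1", "time2"),
                                 subset = c("all", "correct", "incorrect")) {
  reference <- match.arg(reference)
  subset <- match.arg(subset)
  if ("valid" %in% names(trials)) trials <- trials[trials$valid, ]
  correct <- score_toj(trials)
  if (subset == "correct") {
    trials <- trials[correct, ]
  } else if (subset == "incorrect") {
    trials <- trials[!correct, ]
  }
  if (reference == "time2" && subset != "correct") {
    stop_tojshift(
      "the time-2 reference defines the correct-trial template only",
      "tojshift_config_error")
  }
  correct <- score_toj(trials)

  left <- trials$response_hand == "left"
  pick <- function(col_l, col_r) ifelse(left, trials[[col_l]], trials[[col_r]])
  sx <- pick("start_x_left_mm", "start_x_right_mm")
  sy <- pick("start_y_left_mm", "start_y_right_mm")
  ex <- pick("end_x_left_mm", "end_x_right_mm")
  ey <- pick("end_y_left_mm", "end_y_right_mm")
  onset <- pick("onset_left_ms", "onset_right_ms")
  dur <- pick("duration_left_ms", "duration_right_ms")
  path <- sqrt((ex - sx)^2 + (ey - sy)^2)
  if (any(path == 0)) {
    stop_tojshift("onset and offset positions coincide",
                  "tojshift_degenerate_axis")
  }
  ux <- (ex - sx) / path
  uy <- (ey - sy) / path
  rep_proj <- (trials$reported_x_mm - sx) * ux +
    (trials$reported_y_mm - sy) * uy
  t_ref <- if (reference == "time1") trials$t1_ms else trials$t2_ms
  true_proj <- path_position(t_ref, onset, dur, path)

  tibble(
    trial_id = trials$trial_id,
    participant_id = trials$participant_id,
    start_posture = trials$start_posture,
    end_posture = trials$end_posture,
    soa_ms = trials$soa_ms,
    correct = correct,
    reference = reference,
    t = trials$t1_ms - onset,
    error = rep_proj - true_proj,
    rep_proj = rep_proj,
    true_proj = true_proj,
    path_mm = path,
    duration_ms = dur
  )
}

#' Perceived and true distance along the movement path
#'
#' Both quantities are along-axis projections measured from the movement
#' start: the perceived distance is the projected report, the true distance
#' is the hand's projected position at the referenced stimulus time. Their
#' difference is exactly the localization error.
#'
#' @param samples A tibble from [localization_samples()].
#' @return The input with columns `perceived_mm` and `true_mm` appended.
#' @export
perceived_true_distance <- function(samples) {
  samples$perceived_mm <- samples$rep_proj
  samples$true_mm <- samples$true_proj
  samples
}

#' Localization-curve configuration
#'
#' @param grid_start,grid_end,grid_step Time grid (ms relative to movement
#'   onset) on which curves are evaluated.
#' @param kernel_width Standard deviation of the Gaussian smoothing kernel,
#'   ms.
#' @param min_support Minimum effective sample weight (kernel mass, in units
#'   of one on-grid sample) required for the curve to be defined at a grid
#'   point.
#' @return An object of class `curve_config`.
#' @export
curve_config <- function(grid_start = -200, grid_end = 600, grid_step = 1,
                         kernel_width = 75, min_support = 2) {
  stopifnot(grid_start < grid_end, grid_step > 0, kernel_width > 0,
            min_support >= 0)
  structure(list(grid_start = grid_start, grid_end = grid_end,
                 grid_step = grid_step, kernel_width = kernel_width,
                 min_support = min_support),
            class = "curve_config")
}

#' Estimate a smoothed localization-error curve
#'
#' Moving-Gaussian (Nadaraya-Watson) average of localization errors over
#' stimulus time: at each grid point `g` the curve is the kernel-weighted
#' mean of all sample errors, with weights `exp(-0.5 ((g - t_i) /
#' kernel_width)^2)`. The support at `g` is the total kernel weight (in
#' units of one co-located sample); the curve is undefined where the support
#' falls below `min_support`, so data-free regions are not extrapolated.
#' Samples outside the grid still contribute weight near the edges.
#'
#' @param samples Tibble with columns `t` (ms) and `error` (mm), e.g. from
#'   [localization_samples()].
#' @param cfg A [curve_config()].
#' @return A tibble with columns `t`, `value`, `support`, `defined`; the
#'   configuration is attached as attribute `"config"`.
#' @export
estimate_curve <- function(samples, cfg = curve_config()) {
  if (nrow(samples) == 0) {
    stop_tojshift("no samples to smooth", "tojshift_no_data")
  }
  grid <- seq(cfg$grid_start, cfg$grid_end, by = cfg$grid_step)
  w <- exp(-0.5 * (outer(grid, samples$t, "-") / cfg$kernel_width)^2)
  support <- rowSums(w)
  value <- as.vector(w %*% samples$error) / support
  defined <- support >= cfg$min_support
  value[!defined] <- NA_real_
  out <- tibble(t = grid, value = value, support = support,
                defined = defined)
  attr(out, "config") <- cfg
  out
}
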
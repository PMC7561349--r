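#' Hand trajectory specification
#'
#' Describes one hand's reach as a minimum-jerk movement along the straight
#' chord from `start_point` to `end_point`, beginning at `onset_time` (ms
#' after the trial cue) and lasting `duration` ms. Positions are planar
#' (x lateral, rightward positive; y along the table, movement direction is
#' toward the body, i.e. decreasing y), in mm.
#'
#' @param start_point,end_point Numeric length-2 vectors, (x, y) in mm.
#' @param onset_time Movement onset in ms relative to the trial cue.
#' @param duration Movement duration in ms; must be positive.
#' @return An object of class `hand_trajectory_spec`.
#' @examples
#' spec <- hand_trajectory_spec(c(-100, 400), c(-100, 100), 250, 500)
#' min_jerk_position(c(250, 500, 750), spec)
#' @export
hand_trajectory_spec <- function(start_point, end_point, onset_time, duration) {
  if (!is.numeric(start_point) || length(start_point) != 2 ||
      !is.numeric(end_point) || length(end_point) != 2) {
    stop_tojshift("start_point and end_point must be numeric (x, y) pairs",
                  "tojshift_invalid_spec")
  }
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0) {
    stop_tojshift("duration must be a single positive number",
                  "tojshift_invalid_spec")
  }
  if (all(start_point == end_point)) {
    stop_tojshift("start and end point coincide", "tojshift_invalid_spec")
  }
  structure(
    list(start_point = as.numeric(start_point),
         end_point = as.numeric(end_point),
         onset_time = as.numeric(onset_time),
         duration = as.numeric(duration)),
    class = "hand_trajectory_spec"
  )
}

## quintic minimum-jerk progress profile on [0, 1], clamped outside
min_jerk_shape <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 + x * (-15 + 6 * x))
}

## derivative of the progress profile (per unit normalized time)
min_jerk_shape_deriv <- function(x) {
  inside <- x > 0 & x < 1
  out <- numeric(length(x))
  xi <- x[inside]
  out[inside] <- 30 * xi^2 - 60 * xi^3 + 30 * xi^4
  out
}

#' Evaluate a minimum-jerk trajectory
#'
#' Position of the hand at times `t` (ms after the trial cue). Before
#' movement onset the hand rests at the start point; after the offset it
#' rests at the end point; within the movement it follows the classic
#' quintic minimum-jerk profile along the start-to-end chord, which is
#' C2-smooth and strictly monotone in path progress.
#'
#' @param t Numeric vector of times, ms after the cue.
#' @param spec A [hand_trajectory_spec()].
#' @return A numeric matrix with `length(t)` rows and columns `x`, `y` (mm).
#' @examples
#' spec <- hand_trajectory_spec(c(0, 400), c(0, 100), 0, 500)
#' min_jerk_position(250, spec)  # midpoint at mid-movement
#' @export
min_jerk_position <- function(t, spec) {
  stopifnot(inherits(spec, "hand_trajectory_spec"))
  h <- min_jerk_shape((t - spec$onset_time) / spec$duration)
  d <- spec$end_point - spec$start_point
  cbind(x = spec$start_point[1] + h * d[1],
        y = spec$start_point[2] + h * d[2])
}

#' Speed along a minimum-jerk trajectory
#'
#' Tangential speed in mm/ms. The peak is `1.875 * L / duration` (with `L`
#' the chord length) at mid-movement.
#'
#' @inheritParams min_jerk_position
#' @return Numeric vector of speeds, mm/ms.
#' @export
min_jerk_speed <- function(t, spec) {
  stopifnot(inherits(spec, "hand_trajectory_spec"))
  len <- sqrt(sum((spec$end_point - spec$start_point)^2))
  len / spec$duration *
    min_jerk_shape_deriv((t - spec$onset_time) / spec$duration)
}

## along-path position (mm from start) at times t for vectorized trial data;
## used by the analytic localization/shift machinery. path: chord length mm.
path_position <- function(t, onset, duration, path) {
  path * min_jerk_shape((t - onset) / duration)
}

#' Sample a trajectory as a marker table
#'
#' Renders a [hand_trajectory_spec()] into the tidy trajectory-table format
#' used throughout the package (columns `trial_id`, `hand`, `t_ms`, `x_mm`,
#' `y_mm`), optionally with additive Gaussian marker noise and randomly
#' dropped samples (gaps, recorded as `NA`), emulating optical motion
#' capture output.
#'
#' @param spec A [hand_trajectory_spec()].
#' @param trial_id,hand Identifiers stored in the table.
#' @param sampling_rate Sampling rate in Hz.
#' @param t_end Last sample time, ms after cue; defaults to 200 ms past the
#'   movement offset.
#' @param noise_sd Marker noise standard deviation, mm.
#' @param gap_prob Per-sample probability of a missing (NA) position.
#' @return A tibble with one row per sample.
#' @export
sample_trajectory <- function(spec, trial_id = 1L, hand = "left",
                              sampling_rate = 250, t_end = NULL,
                              noise_sd = 0, gap_prob = 0) {
  if (is.null(t_end)) t_end <- spec$onset_time + spec$duration + 200
  ts <- seq(0, t_end, by = 1000 / sampling_rate)
  pos <- min_jerk_position(ts, spec)
  if (noise_sd > 0) {
    pos <- pos + matrix(rnorm(length(pos), 0, noise_sd), ncol = 2)
  }
  if (gap_prob > 0) {
    gap <- runif(length(ts)) < gap_prob
    pos[gap, ] <- NA_real_
  }
  tibble(trial_id = trial_id, hand = hand, t_ms = ts,
         x_mm = pos[, 1], y_mm = pos[, 2])
}
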
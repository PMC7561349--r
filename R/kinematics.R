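#' Kinematic preprocessing configuration
#'
#' Parameters of the trajectory preprocessing chain and of the trial
#' exclusion rules. Defaults follow standard motion-capture practice for
#' reach data: movement bounds detected at a 5 cm/s (0.05 mm/ms) resultant
#' velocity threshold, a zero-phase second-order Butterworth low-pass at
#' 6 Hz after spline resampling to 1000 Hz, and exclusion of trials whose
#' movements are shorter than 200 ms, longer than 1000 ms, asynchronous
#' across hands by more than `sync_tolerance`, or non-smooth (more than one
#' suprathreshold velocity episode).
#'
#' @param velocity_threshold Onset/offset threshold, mm/ms.
#' @param filter_order Butterworth order (applied forward and backward).
#' @param filter_cutoff Low-pass cutoff, Hz.
#' @param resample_rate Target uniform sampling rate, Hz.
#' @param min_duration,max_duration Admissible movement duration, ms.
#' @param sync_tolerance Maximum onset difference between the hands, ms.
#' @param max_gap Longest marker gap that may be interpolated, ms.
#' @return An object of class `kinematics_config`.
#' @export
kinematics_config <- function(velocity_threshold = 0.05,
                              filter_order = 2,
                              filter_cutoff = 6,
                              resample_rate = 1000,
                              min_duration = 200,
                              max_duration = 1000,
                              sync_tolerance = 150,
                              max_gap = 50) {
  stopifnot(velocity_threshold > 0, filter_cutoff > 0, resample_rate > 0,
            min_duration < max_duration, max_gap > 0, sync_tolerance > 0)
  structure(list(velocity_threshold = velocity_threshold,
                 filter_order = filter_order,
                 filter_cutoff = filter_cutoff,
                 resample_rate = resample_rate,
                 min_duration = min_duration,
                 max_duration = max_duration,
                 sync_tolerance = sync_tolerance,
                 max_gap = max_gap),
            class = "kinematics_config")
}

## position column names of a trajectory table (z optional)
.pos_cols <- function(traj) intersect(c("x_mm", "y_mm", "z_mm"), names(traj))

#' Interpolate marker gaps with cubic splines
#'
#' Fills `NA` runs in the position columns of a single-hand trajectory table
#' using cubic splines through the valid samples. Gaps at either end of the
#' recording, or longer than `max_gap` ms, cannot be restored reliably and
#' signal a `tojshift_not_interpolatable` condition (such trials are later
#' excluded).
#'
#' @param traj Tibble with columns `t_ms` (strictly increasing) and position
#'   columns `x_mm`, `y_mm` (optionally `z_mm`), possibly containing `NA`.
#' @param max_gap Longest admissible gap, ms.
#' @return The trajectory with all gaps filled; valid samples are unchanged.
#' @export
interpolate_gaps <- function(traj, max_gap = 50) {
  cols <- .pos_cols(traj)
  miss <- Reduce(`|`, lapply(traj[cols], is.na))
  if (!any(miss)) return(traj)
  if (sum(!miss) < 4) {
    stop_tojshift("fewer than 4 valid samples", "tojshift_not_interpolatable")
  }
  if (miss[1] || miss[length(miss)]) {
    stop_tojshift("marker gap at the start or end of the recording",
                  "tojshift_not_interpolatable")
  }
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in which(runs$values)) {
    ## gap duration measured between the flanking valid samples
    gap_ms <- traj$t_ms[ends[r] + 1] - traj$t_ms[starts[r] - 1]
    if (gap_ms >= max_gap) {
      stop_tojshift(sprintf("marker gap of %.1f ms exceeds max_gap", gap_ms),
                    "tojshift_not_interpolatable")
    }
  }
  ok <- !miss
  for (cl in cols) {
    f <- splinefun(traj$t_ms[ok], traj[[cl]][ok], method = "fmm")
    traj[[cl]][miss] <- f(traj$t_ms[miss])
  }
  traj
}

## zero-phase Butterworth low-pass with reflection padding
.zero_phase_lowpass <- function(x, order, cutoff, fs) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- min(length(x) - 1, max(3 * round(fs / cutoff), 3 * order))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[length(x)] - rev(x[(length(x) - pad):(length(x) - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + length(x))]
}

#' Resample and low-pass filter a trajectory
#'
#' Spline-resamples a gap-free single-hand trajectory to a uniform time base
#' at `resample_rate` Hz, then applies the Butterworth low-pass forward and
#' backward (zero phase, so movement onsets are not delayed), with
#' reflection padding at the ends.
#'
#' @param traj Gap-free trajectory tibble (columns `t_ms` and positions).
#' @param cfg A [kinematics_config()].
#' @return The filtered trajectory on the uniform time base.
#' @export
resample_and_filter <- function(traj, cfg = kinematics_config()) {
  cols <- .pos_cols(traj)
  if (anyNA(traj[cols])) {
    stop_tojshift("trajectory contains gaps; interpolate first",
                  "tojshift_not_interpolatable")
  }
  fs <- cfg$resample_rate
  ts <- seq(min(traj$t_ms), max(traj$t_ms), by = 1000 / fs)
  if (length(ts) <= 6 * cfg$filter_order + 1) {
    stop_tojshift("trajectory too short for filtering", "tojshift_too_short")
  }
  out <- tibble(t_ms = ts)
  for (cl in cols) {
    xi <- spline(traj$t_ms, traj[[cl]], xout = ts, method = "fmm")$y
    out[[cl]] <- .zero_phase_lowpass(xi, cfg$filter_order, cfg$filter_cutoff,
                                     fs)
  }
  for (cl in setdiff(c("trial_id", "hand"), character(0))) {
    if (cl %in% names(traj)) out[[cl]] <- traj[[cl]][1]
  }
  out
}

## resultant (vector-norm) velocity via central differences, one-sided ends
.resultant_velocity <- function(traj) {
  cols <- .pos_cols(traj)
  tt <- traj$t_ms
  n <- length(tt)
  v2 <- 0
  for (cl in cols) {
    x <- traj[[cl]]
    dx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
    dt <- c(tt[2] - tt[1], (tt[3:n] - tt[1:(n - 2)]) / 2, tt[n] - tt[n - 1])
    v2 <- v2 + (dx / dt)^2
  }
  sqrt(v2)
}

#' Detect movement onset and offset from a velocity threshold
#'
#' Onset is the time of the first sample whose resultant velocity exceeds
#' `v_thr`; offset is the first sample after the velocity peak at which the
#' resultant velocity drops back below `v_thr`. A trajectory whose velocity
#' never exceeds the threshold signals `tojshift_no_movement`; more than one
#' suprathreshold episode separated by over 200 ms signals
#' `tojshift_non_smooth` (the trial is excluded as a non-smooth movement).
#'
#' @param traj Filtered, uniformly sampled single-hand trajectory.
#' @param v_thr Velocity threshold, mm/ms (default 0.05 = 5 cm/s).
#' @return A list with elements `onset` and `offset` (ms).
#' @export
detect_onset_offset <- function(traj, v_thr = 0.05) {
  v <- .resultant_velocity(traj)
  above <- v > v_thr
  if (!any(above)) {
    stop_tojshift("velocity never exceeds the threshold",
                  "tojshift_no_movement")
  }
  ## episodes of suprathreshold velocity
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  epi <- which(runs$values)
  if (length(epi) > 1) {
    gaps <- traj$t_ms[starts[epi][-1]] - traj$t_ms[ends[epi][-length(epi)]]
    if (any(gaps > 200)) {
      stop_tojshift("multiple movement episodes separated by more than 200 ms",
                    "tojshift_non_smooth")
    }
  }
  onset_i <- which(above)[1]
  peak_i <- which.max(v)
  after <- which(!above & seq_along(v) > peak_i)
  offset_i <- if (length(after)) after[1] else length(v)
  list(onset = traj$t_ms[onset_i], offset = traj$t_ms[offset_i])
}

#' Time of the postural change of a bimanual reach
#'
#' The postural change is the instant at which the two hands pass each other
#' laterally, operationalized as the sign change of `x_left - x_right`
#' (linearly interpolated between samples). Returns `NA` when the lateral
#' order of the hands never changes. If several sign changes occur the first
#' is returned, with attribute `flagged = TRUE`.
#'
#' @param left,right Preprocessed single-hand trajectories of the same trial.
#' @return Crossing time in ms, or `NA_real_`.
#' @export
detect_postural_change <- function(left, right) {
  t0 <- max(min(left$t_ms), min(right$t_ms))
  t1 <- min(max(left$t_ms), max(right$t_ms))
  ts <- seq(t0, t1, length.out = max(64, min(nrow(left), nrow(right))))
  dx <- approx(left$t_ms, left$x_mm, xout = ts)$y -
    approx(right$t_ms, right$x_mm, xout = ts)$y
  sgn <- sign(dx)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    z <- which(sgn == 0)
    if (!length(z)) return(NA_real_)
    return(ts[z[1]])
  }
  i <- flip[1]
  ## linear interpolation of the zero crossing
  cross <- ts[i] + (ts[i + 1] - ts[i]) * dx[i] / (dx[i] - dx[i + 1])
  if (length(flip) > 1) attr(cross, "flagged") <- TRUE
  cross
}

#' Apply the trial exclusion rules
#'
#' Classifies one trial as valid or excluded for exactly one reason, checked
#' in order: `interpolation` (marker gaps could not be restored, signalled
#' upstream and passed in via `interpolation_failed`), `response` (no
#' reported location), `duration` (either hand's movement outside
#' `[min_duration, max_duration]`), `asynchrony` (hand onsets differ by more
#' than `sync_tolerance`), `smoothness` (non-smooth velocity profile,
#' signalled upstream via `non_smooth`).
#'
#' @param trial One-row trial tibble (needs `reported_x_mm`,
#'   `reported_y_mm`).
#' @param bounds_left,bounds_right Lists with `onset`/`offset` (ms) per hand,
#'   or `NULL` when detection failed.
#' @param cfg A [kinematics_config()].
#' @param interpolation_failed,non_smooth Logical flags from preprocessing.
#' @return A list with `valid` (logical) and `reason` (one of `"valid"`,
#'   `"interpolation"`, `"response"`, `"duration"`, `"asynchrony"`,
#'   `"smoothness"`).
#' @export
apply_exclusions <- function(trial, bounds_left, bounds_right,
                             cfg = kinematics_config(),
                             interpolation_failed = FALSE,
                             non_smooth = FALSE) {
  res <- function(reason) list(valid = reason == "valid", reason = reason)
  if (interpolation_failed) return(res("interpolation"))
  if (is.na(trial$reported_x_mm) || is.na(trial$reported_y_mm)) {
    return(res("response"))
  }
  if (non_smooth || is.null(bounds_left) || is.null(bounds_right)) {
    return(res("smoothness"))
  }
  dur_l <- bounds_left$offset - bounds_left$onset
  dur_r <- bounds_right$offset - bounds_right$onset
  if (dur_l < cfg$min_duration || dur_l > cfg$max_duration ||
      dur_r < cfg$min_duration || dur_r > cfg$max_duration) {
    return(res("duration"))
  }
  if (abs(bounds_left$onset - bounds_right$onset) > cfg$sync_tolerance) {
    return(res("asynchrony"))
  }
  res("valid")
}

#' Preprocess all trajectories of a dataset
#'
#' Runs the full chain per trial and hand - gap interpolation, resampling,
#' zero-phase filtering, onset/offset detection, postural-change detection -
#' and applies the exclusion rules. Trial annotations (`onset_*`,
#' `offset_*`, `duration_*`, `postural_change_ms`) are replaced by the
#' detected values for valid trials.
#'
#' @param trials Trial tibble.
#' @param trajectories Tidy trajectory table (`trial_id`, `hand`, `t_ms`,
#'   `x_mm`, `y_mm`).
#' @param cfg A [kinematics_config()].
#' @return A list with `trials` (annotated, with `valid` and
#'   `exclusion_reason` columns) and `trajectories` (preprocessed, valid
#'   trials only).
#' @export
preprocess_trajectories <- function(trials, trajectories,
                                    cfg = kinematics_config()) {
  stopifnot(all(c("trial_id", "hand", "t_ms", "x_mm", "y_mm") %in%
                  names(trajectories)))
  trials$valid <- TRUE
  trials$exclusion_reason <- "valid"
  out_traj <- vector("list", nrow(trials))
  by_trial <- split(trajectories, trajectories$trial_id)

  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    tr <- by_trial[[id]]
    interp_failed <- FALSE
    smooth_failed <- FALSE
    bounds <- list(left = NULL, right = NULL)
    proc <- list(left = NULL, right = NULL)
    for (h in c("left", "right")) {
      th <- tr[tr$hand == h, , drop = FALSE]
      ok <- tryCatch({
        th <- interpolate_gaps(th, cfg$max_gap)
        th <- resample_and_filter(th, cfg)
        bounds[[h]] <- detect_onset_offset(th, cfg$velocity_threshold)
        proc[[h]] <- th
        TRUE
      },
      tojshift_not_interpolatable = function(e) {
        interp_failed <<- TRUE; FALSE
      },
      tojshift_non_smooth = function(e) {
        smooth_failed <<- TRUE; FALSE
      },
      tojshift_no_movement = function(e) {
        smooth_failed <<- TRUE; FALSE
      },
      tojshift_too_short = function(e) {
        interp_failed <<- TRUE; FALSE
      })
      if (!ok) break
    }
    dec <- apply_exclusions(trials[i, ], bounds$left, bounds$right, cfg,
                            interpolation_failed = interp_failed,
                            non_smooth = smooth_failed)
    trials$valid[i] <- dec$valid
    trials$exclusion_reason[i] <- dec$reason
    if (dec$valid) {
      trials$onset_left_ms[i] <- bounds$left$onset
      trials$offset_left_ms[i] <- bounds$left$offset
      trials$duration_left_ms[i] <- bounds$left$offset - bounds$left$onset
      trials$onset_right_ms[i] <- bounds$right$onset
      trials$offset_right_ms[i] <- bounds$right$offset
      trials$duration_right_ms[i] <- bounds$right$offset - bounds$right$onset
      ## movement axis endpoints from the filtered data themselves
      for (h in c("left", "right")) {
        th <- proc[[h]]
        b <- bounds[[h]]
        trials[[paste0("start_x_", h, "_mm")]][i] <-
          approx(th$t_ms, th$x_mm, xout = b$onset)$y
        trials[[paste0("start_y_", h, "_mm")]][i] <-
          approx(th$t_ms, th$y_mm, xout = b$onset)$y
        trials[[paste0("end_x_", h, "_mm")]][i] <-
          approx(th$t_ms, th$x_mm, xout = b$offset)$y
        trials[[paste0("end_y_", h, "_mm")]][i] <-
          approx(th$t_ms, th$y_mm, xout = b$offset)$y
      }
      if (trials$start_posture[i] != trials$end_posture[i]) {
        pc <- detect_postural_change(proc$left, proc$right)
        trials$postural_change_ms[i] <- as.numeric(pc)
      }
      out_traj[[i]] <- bind_rows(proc$left, proc$right)
    }
  }
  list(trials = trials, trajectories = bind_rows(out_traj))
}
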
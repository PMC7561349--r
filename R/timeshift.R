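#' Time-shift estimation configuration
#'
#' @param shift_min,shift_max,shift_step Candidate shift grid, ms; the grid
#'   must straddle zero.
#' @param min_incorrect_trials Minimum number of incorrect-TOJ trials for a
#'   cell to yield a valid estimate; below the floor the estimate is
#'   reported as missing.
#' @param shift_method How a candidate shift `s` is applied to the incorrect
#'   samples before the pooled common curve and the summed squared
#'   deviations are computed:
#'   * `"reference"` (default): each incorrect trial's error is re-derived
#'     against its own hand's position at the reference time displaced by
#'     `s` (sample times stay put). `s = 0` reproduces the time-1 error
#'     construction and `s = -SOA` reproduces the time-2 construction
#'     exactly, so the estimate reads directly as "which reference timing
#'     makes the incorrect trials consistent with the template". Negative
#'     values displace the incorrect-trial curve leftward/backward, matching
#'     the template curves' ordering.
#'   * `"sliding"`: the incorrect samples' time coordinates are displaced by
#'     `+s` with errors untouched, and candidate shifts leaving less than
#'     `min_overlap` of the pooled samples on supported curve regions are
#'     disallowed.
#' @param min_overlap Minimum fraction of pooled samples with defined curve
#'   support (sliding method only).
#' @param curve A [curve_config()] for the common curve.
#' @return An object of class `shift_config`.
#' @export
shift_config <- function(shift_min = -300, shift_max = 300, shift_step = 1,
                         min_incorrect_trials = 5,
                         shift_method = c("reference", "sliding"),
                         min_overlap = 0.8,
                         curve = curve_config()) {
  stopifnot(shift_min < 0, shift_max > 0, shift_step > 0)
  if (abs((shift_max - shift_min) / shift_step -
            round((shift_max - shift_min) / shift_step)) > 1e-9) {
    stop_tojshift("shift_step must divide the shift range",
                  "tojshift_config_error")
  }
  structure(list(shift_min = shift_min, shift_max = shift_max,
                 shift_step = shift_step,
                 min_incorrect_trials = min_incorrect_trials,
                 shift_method = match.arg(shift_method),
                 min_overlap = min_overlap,
                 curve = curve),
            class = "shift_config")
}

## re-derived incorrect-trial errors for a matrix of shifts:
## e_i(s) = rep_proj_i - D_i(t_i - s), D_i the hand's along-path position
.rederived_errors <- function(incorrect, shifts) {
  tau <- outer(incorrect$t, shifts, "-")  # n_i x n_shift
  h <- min_jerk_shape(tau / incorrect$duration_ms)
  incorrect$rep_proj - incorrect$path_mm * h
}

## cost profile, reference method: pooled times are fixed, so the kernel
## matrix is computed once; only the incorrect errors vary with the shift
.profile_reference <- function(correct, incorrect, shifts, cfg) {
  tc <- correct$t
  ec <- correct$error
  ti <- incorrect$t
  kw <- cfg$curve$kernel_width
  tp <- c(tc, ti)
  K <- exp(-0.5 * (outer(tp, tp, "-") / kw)^2)
  sup <- rowSums(K)
  ok <- sup >= cfg$curve$min_support
  if (!any(ok)) stop_tojshift("pooled support empty", "tojshift_no_overlap")
  nc <- length(tc)
  E <- .rederived_errors(incorrect, shifts)        # n_i x S
  Vc <- as.vector(K[, seq_len(nc), drop = FALSE] %*% ec)
  V <- (Vc + K[, nc + seq_along(ti), drop = FALSE] %*% E) / sup
  Efull <- rbind(matrix(ec, nc, length(shifts)), E)
  list(cost = colSums(((Efull - V)^2)[ok, , drop = FALSE]),
       overlap = rep(mean(ok), length(shifts)))
}

## cost profile, sliding method: times move, kernel recomputed per shift
.profile_sliding <- function(correct, incorrect, shifts, cfg) {
  tc <- correct$t
  ec <- correct$error
  ti <- incorrect$t
  ei <- incorrect$error
  kw <- cfg$curve$kernel_width
  e <- c(ec, ei)
  cost <- numeric(length(shifts))
  overlap <- numeric(length(shifts))
  for (j in seq_along(shifts)) {
    tp <- c(tc, ti + shifts[j])
    K <- exp(-0.5 * (outer(tp, tp, "-") / kw)^2)
    sup <- rowSums(K)
    ok <- sup >= cfg$curve$min_support
    v <- as.vector(K %*% e) / sup
    cost[j] <- sum(((e - v)^2)[ok])
    overlap[j] <- mean(ok)
  }
  if (all(overlap == 0)) {
    stop_tojshift("pooled support empty", "tojshift_no_overlap")
  }
  list(cost = cost, overlap = overlap)
}

#' Cost of a single candidate time shift
#'
#' Applies the shift `s` to the incorrect samples (see
#' [shift_config()]`$shift_method`), estimates one common moving-Gaussian
#' curve from the pooled correct and shifted-incorrect samples, and returns
#' the summed squared deviations of all pooled samples from that curve.
#' Samples at grid regions without curve support contribute zero and the
#' supported fraction is recorded as attribute `"overlap"`.
#'
#' @param correct Template samples (a [localization_samples()] tibble).
#' @param incorrect Incorrect-trial samples (reference `"time1"`).
#' @param s Candidate shift, ms.
#' @param cfg A [shift_config()].
#' @return Cost in mm^2, with attribute `overlap`.
#' @export
common_curve_cost <- function(correct, incorrect, s, cfg = shift_config()) {
  stopifnot(nrow(correct) > 0, nrow(incorrect) > 0)
  prof <- if (cfg$shift_method == "reference") {
    .profile_reference(correct, incorrect, s, cfg)
  } else {
    .profile_sliding(correct, incorrect, s, cfg)
  }
  structure(prof$cost, overlap = prof$overlap)
}

#' Estimate the time shift aligning incorrect trials with a template
#'
#' Scans the configured grid of candidate shifts, computing
#' [common_curve_cost()] at each, and returns the shift minimizing the cost
#' (ties broken toward the smallest absolute shift). With the default
#' reference method the estimate answers: by how much must the incorrect
#' trials' reference time be displaced for their localization errors to be
#' maximally consistent with the template curve? Under time reconstruction
#' the expected estimates are 0 against the time-1 template and -SOA against
#' the time-2 template.
#'
#' Cells with fewer than `min_incorrect_trials` incorrect trials yield
#' `valid = FALSE` (treated as missing downstream).
#'
#' @inheritParams common_curve_cost
#' @return An object of class `time_shift_estimate`: a list with `shift`,
#'   `valid`, `n_correct`, `n_incorrect`, `shifts`, `cost_profile`,
#'   `overlap`.
#' @export
estimate_time_shift <- function(correct, incorrect, cfg = shift_config()) {
  stopifnot(nrow(incorrect) >= 1)
  shifts <- seq(cfg$shift_min, cfg$shift_max, by = cfg$shift_step)
  prof <- if (cfg$shift_method == "reference") {
    .profile_reference(correct, incorrect, shifts, cfg)
  } else {
    .profile_sliding(correct, incorrect, shifts, cfg)
  }
  cost <- prof$cost
  if (cfg$shift_method == "sliding") {
    cost[prof$overlap < cfg$min_overlap] <- Inf
  }
  if (!any(is.finite(cost))) {
    stop_tojshift("no candidate shift satisfies the overlap requirement",
                  "tojshift_no_overlap")
  }
  ## ties (within floating-point resolution of the cost) break toward |s| = 0
  cmin <- min(cost)
  best <- which(cost <= cmin + 1e-12 * max(abs(cmin), 1))
  best <- best[order(abs(shifts[best]), shifts[best])][1]
  structure(
    list(shift = shifts[best],
         valid = nrow(incorrect) >= cfg$min_incorrect_trials,
         n_correct = nrow(correct),
         n_incorrect = nrow(incorrect),
         shifts = shifts,
         cost_profile = prof$cost,
         overlap = prof$overlap),
    class = "time_shift_estimate"
  )
}

#' @export
print.time_shift_estimate <- function(x, ...) {
  cat(sprintf(
    "time shift: %g ms (%s; %d correct / %d incorrect trials)\n",
    x$shift, if (x$valid) "valid" else "below incorrect-trial floor",
    x$n_correct, x$n_incorrect))
  invisible(x)
}

#' Per-cell time-shift table
#'
#' Estimates the time shift for every analysis cell and both reference time
#' points. Cells are participant x posture condition (`by = "condition"`) or
#' participant x SOA with postures collapsed (`by = "soa"`, the multi-SOA
#' design). Cells whose estimate is unavailable (too few incorrect trials)
#' are kept as missing rows rather than dropped.
#'
#' @param trials Trial tibble (valid trials only are used).
#' @param cfg A [shift_config()].
#' @param by `"condition"` or `"soa"`.
#' @return A tibble with one row per cell and reference.
#' @export
shift_table <- function(trials, cfg = shift_config(),
                        by = c("condition", "soa")) {
  by <- match.arg(by)
  if ("valid" %in% names(trials)) trials <- trials[trials$valid, ]
  keys <- if (by == "condition") {
    c("participant_id", "start_posture", "end_posture")
  } else {
    c("participant_id", "soa_ms")
  }
  cells <- unique(trials[keys])
  cells <- cells[do.call(order, as.list(cells)), , drop = FALSE]
  rows <- vector("list", 2 * nrow(cells))
  k <- 0
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(trials))
    for (key in keys) sel <- sel & trials[[key]] == cells[[key]][i]
    cell_trials <- trials[sel, ]
    incorrect <- localization_samples(cell_trials, "time1", "incorrect")
    for (ref in c("time1", "time2")) {
      correct <- localization_samples(cell_trials, ref, "correct")
      est <- NULL
      if (nrow(incorrect) >= 1 && nrow(correct) >= 1) {
        est <- tryCatch(estimate_time_shift(correct, incorrect, cfg),
                        tojshift_no_overlap = function(e) NULL)
      }
      k <- k + 1
      rows[[k]] <- tibble(
        cells[i, , drop = FALSE],
        reference = ref,
        n_correct = nrow(correct),
        n_incorrect = nrow(incorrect),
        shift_ms = if (!is.null(est) && est$valid) est$shift else NA_real_,
        valid = !is.null(est) && est$valid
      )
    }
  }
  bind_rows(rows)
}

#' Bootstrap test of the mean time shift
#'
#' Participant-level percentile bootstrap of the mean shift for one
#' reference time point: participants are resampled with replacement and
#' each contributes the mean of their valid cell shifts. Reports the
#' observed mean, a percentile confidence interval and a two-sided p-value
#' for the null `mean == h0`. Deterministic given `seed`.
#'
#' @param table A [shift_table()].
#' @param reference `"time1"` or `"time2"`.
#' @param h0 Null value of the mean shift, ms.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A list with `mean_shift`, `ci`, `p_value`, `n_participants`,
#'   `n_cells`.
#' @export
bootstrap_shift_test <- function(table, reference = "time1", h0 = 0,
                                 n_boot = 2000, seed = 1L, conf = 0.95) {
  tab <- table[table$reference == reference & table$valid &
                 is.finite(table$shift_ms), ]
  if (nrow(tab) == 0) {
    stop_tojshift("no valid shift estimates", "tojshift_no_data")
  }
  per_p <- tapply(tab$shift_ms, tab$participant_id, mean)
  n <- length(per_p)
  if (n < 2) {
    stop_tojshift("need at least two participants with valid estimates",
                  "tojshift_no_data")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(per_p[sample.int(n, n, replace = TRUE)])
  }, 0)
  alpha <- 1 - conf
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  p <- 2 * min(mean(boot <= h0), mean(boot >= h0))
  list(mean_shift = mean(per_p), ci = ci, p_value = min(1, p),
       n_participants = n, n_cells = nrow(tab))
}

#' Classify the generating hypothesis from a shift pair
#'
#' Nearest-signature classification of the `(shift vs time-1 template,
#' shift vs time-2 template)` pair, in Euclidean distance. The signatures
#' depend on how the statistic applies shifts (see [shift_config()]):
#' * reference method - time reconstruction `(0, -SOA)`, stimulus switch
#'   `(-SOA, -2 SOA)` (the stimulus-switch reports aim one SOA later than
#'   the time-1 label, which this statistic reads as a reference delayed by
#'   the SOA against either template);
#' * sliding method - time reconstruction `(0, -SOA)`, stimulus switch
#'   `(+SOA, 0)` (the idealized curve-translation picture).
#'
#' The space-to-limb account predicts reports on the wrong hand's path and
#' is detected upstream by [lateral_distance_test()]; it has no shift
#' signature here.
#'
#' @param shift_t1,shift_t2 Estimated shifts (ms) against the time-1 and
#'   time-2 templates.
#' @param soa Stimulus onset asynchrony, ms.
#' @param method Signature set to use; match the `shift_method` that
#'   produced the estimates.
#' @return `"time_reconstruction"`, `"stimulus_switch"`, `"ambiguous"`
#'   (equidistant) or `"unclassifiable"` (missing input).
#' @export
classify_hypothesis <- function(shift_t1, shift_t2, soa,
                                method = c("reference", "sliding")) {
  method <- match.arg(method)
  if (!is.finite(shift_t1) || !is.finite(shift_t2)) return("unclassifiable")
  sig <- if (method == "reference") {
    list(time_reconstruction = c(0, -soa),
         stimulus_switch = c(-soa, -2 * soa))
  } else {
    list(time_reconstruction = c(0, -soa),
         stimulus_switch = c(soa, 0))
  }
  d <- vapply(sig, function(s) {
    sqrt((shift_t1 - s[1])^2 + (shift_t2 - s[2])^2)
  }, 0)
  if (abs(diff(d)) < 1e-9) return("ambiguous")
  names(sig)[which.min(d)]
}

## perpendicular distance of points to the line through (sx,sy)-(ex,ey)
.line_distance <- function(px, py, sx, sy, ex, ey) {
  ux <- ex - sx
  uy <- ey - sy
  len <- sqrt(ux^2 + uy^2)
  abs((px - sx) * (uy / len) - (py - sy) * (ux / len))
}

#' Which hand's path do incorrect-trial reports follow?
#'
#' The space-to-limb reconstruction account predicts that reports on
#' incorrect TOJ trials land on the *correct* hand's movement path (the
#' correctly remapped first-stimulus location), whereas the other two
#' accounts predict reports along the chosen hand's path. This diagnostic
#' compares, across incorrect trials, the perpendicular (lateral) distance
#' of each report to the chosen hand's movement line and to the correct
#' hand's line, and tests the paired mean difference with a sign-flip
#' permutation test.
#'
#' @param trials Trial tibble.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return A list with `mean_dist_chosen`, `mean_dist_correct`, `diff`
#'   (chosen minus correct), `nearer` (`"chosen"` or `"correct"`),
#'   `p_value` (two-sided) and `n`.
#' @export
lateral_distance_test <- function(trials, n_perm = 1000, seed = 1L) {
  if ("valid" %in% names(trials)) trials <- trials[trials$valid, ]
  inc <- trials[!score_toj(trials), ]
  if (nrow(inc) == 0) {
    stop_tojshift("no incorrect trials", "tojshift_no_data")
  }
  left <- inc$response_hand == "left"
  pick <- function(col_l, col_r) ifelse(left, inc[[col_l]], inc[[col_r]])
  d_chosen <- .line_distance(inc$reported_x_mm, inc$reported_y_mm,
                             pick("start_x_left_mm", "start_x_right_mm"),
                             pick("start_y_left_mm", "start_y_right_mm"),
                             pick("end_x_left_mm", "end_x_right_mm"),
                             pick("end_y_left_mm", "end_y_right_mm"))
  d_correct <- .line_distance(inc$reported_x_mm, inc$reported_y_mm,
                              pick("start_x_right_mm", "start_x_left_mm"),
                              pick("start_y_right_mm", "start_y_left_mm"),
                              pick("end_x_right_mm", "end_x_left_mm"),
                              pick("end_y_right_mm", "end_y_left_mm"))
  delta <- d_chosen - d_correct
  obs <- mean(delta)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    mean(delta * sample(c(-1, 1), length(delta), replace = TRUE))
  }, 0)
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(mean_dist_chosen = mean(d_chosen),
       mean_dist_correct = mean(d_correct),
       diff = obs,
       nearer = if (obs > 0) "correct" else "chosen",
       p_value = p,
       n = nrow(inc))
}
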
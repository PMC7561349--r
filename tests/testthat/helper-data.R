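## Shared fixtures and independent oracles, built in code at test time.

## minimal trial tibble with analytic kinematic annotations; all hands move
## 300 mm toward the body between y = 400 and y = 100, +-100 mm lateral
make_trials <- function(n = 4,
                        first_hand = rep(c("left", "right"), length.out = n),
                        response_hand = first_hand,
                        t1 = seq(100, 700, length.out = n),
                        soa = 110,
                        onset = rep(250, n),
                        duration = rep(500, n),
                        start_posture = "uncrossed",
                        end_posture = "uncrossed",
                        participant_id = "P01",
                        reported = NULL) {
  sxl <- if (start_posture == "crossed") 100 else -100
  exl <- if (end_posture == "crossed") 100 else -100
  pc <- if (start_posture == end_posture) rep(NA_real_, n) else
    onset + duration / 2
  tr <- tibble::tibble(
    trial_id = sprintf("%s_T%03d", participant_id, seq_len(n)),
    participant_id = participant_id,
    start_posture = start_posture, end_posture = end_posture,
    soa_ms = soa, first_hand = first_hand,
    t1_ms = t1, t2_ms = t1 + soa,
    response_hand = response_hand,
    onset_left_ms = onset, duration_left_ms = duration,
    offset_left_ms = onset + duration,
    onset_right_ms = onset, duration_right_ms = duration,
    offset_right_ms = onset + duration,
    start_x_left_mm = sxl, start_y_left_mm = 400,
    end_x_left_mm = exl, end_y_left_mm = 100,
    start_x_right_mm = -sxl, start_y_right_mm = 400,
    end_x_right_mm = -exl, end_y_right_mm = 100,
    postural_change_ms = pc,
    valid = TRUE
  )
  if (is.null(reported)) {
    ## veridical reports: the reporting hand's true position at t1
    left <- tr$response_hand == "left"
    h <- tojshift::min_jerk_position
    rep_pos <- t(vapply(seq_len(n), function(i) {
      spec <- tojshift::hand_trajectory_spec(
        c(ifelse(left[i], sxl, -sxl), 400),
        c(ifelse(left[i], exl, -exl), 100),
        onset[i], duration[i])
      drop(h(tr$t1_ms[i], spec))
    }, c(x = 0, y = 0)))
    reported <- unname(rep_pos)
  }
  tr$reported_x_mm <- unname(reported[, 1])
  tr$reported_y_mm <- unname(reported[, 2])
  tr
}

## analytic along-path position of the shared test geometry
path_pos <- function(t, onset = 250, duration = 500, path = 300) {
  x <- pmin(pmax((t - onset) / duration, 0), 1)
  path * (10 * x^3 - 15 * x^4 + 6 * x^5)
}

## synthetic sample cell on the along-axis abstraction: reports aim at the
## position at (t + aim_offset + temporal noise); errors referenced to
## position at (t + ref_offset). Times are relative to movement onset.
synth_cell <- function(n, aim_offset = 0, ref_offset = 0, duration = 500,
                       path = 300, sd_t = 0, sd_x = 0) {
  t <- runif(n, -200, 550)
  shape <- function(tau) {
    x <- pmin(pmax(tau / duration, 0), 1)
    path * (10 * x^3 - 15 * x^4 + 6 * x^5)
  }
  rep_proj <- shape(t + aim_offset + rnorm(n, 0, sd_t)) + rnorm(n, 0, sd_x)
  tibble::tibble(
    trial_id = sprintf("T%04d", seq_len(n)),
    participant_id = "P01",
    start_posture = "uncrossed", end_posture = "uncrossed",
    soa_ms = 110, correct = TRUE, reference = "time1",
    t = t,
    error = rep_proj - shape(t + ref_offset),
    rep_proj = rep_proj,
    true_proj = shape(t + ref_offset),
    path_mm = path,
    duration_ms = duration
  )
}

## ---- independent from-scratch oracles for the shift machinery ------------

## Nadaraya-Watson curve value at arbitrary times (plain formula)
oracle_curve_at <- function(at, t, e, kw) {
  vapply(at, function(g) {
    w <- exp(-0.5 * ((g - t) / kw)^2)
    sum(w * e) / sum(w)
  }, 0)
}

## naive reference-method cost profile: for every shift, re-derive each
## incorrect error from scratch, rebuild the pooled curve sample by sample,
## and sum squared deviations over supported points
oracle_profile_reference <- function(correct, incorrect, shifts, cfg) {
  kw <- cfg$curve$kernel_width
  tp <- c(correct$t, incorrect$t)
  sup <- vapply(tp, function(g) sum(exp(-0.5 * ((g - tp) / kw)^2)), 0)
  ok <- sup >= cfg$curve$min_support
  vapply(shifts, function(s) {
    shape <- function(tau, dur, path) {
      x <- pmin(pmax(tau / dur, 0), 1)
      path * (10 * x^3 - 15 * x^4 + 6 * x^5)
    }
    ei <- vapply(seq_len(nrow(incorrect)), function(i) {
      incorrect$rep_proj[i] -
        shape(incorrect$t[i] - s, incorrect$duration_ms[i],
              incorrect$path_mm[i])
    }, 0)
    e <- c(correct$error, ei)
    v <- oracle_curve_at(tp, tp, e, kw)
    sum(((e - v)^2)[ok])
  }, 0)
}

## naive sliding-method cost profile (double loop over pooled samples)
oracle_profile_sliding <- function(correct, incorrect, shifts, cfg) {
  kw <- cfg$curve$kernel_width
  e <- c(correct$error, incorrect$error)
  vapply(shifts, function(s) {
    tp <- c(correct$t, incorrect$t + s)
    cost <- 0
    for (j in seq_along(tp)) {
      w <- exp(-0.5 * ((tp[j] - tp) / kw)^2)
      if (sum(w) >= cfg$curve$min_support) {
        cost <- cost + (e[j] - sum(w * e) / sum(w))^2
      }
    }
    cost
  }, 0)
}

## small simulated dataset with trials marked valid
quick_dataset <- function(..., seed = 1) {
  cfg <- sim_config(..., seed = seed)
  dat <- generate_dataset(cfg, include_trajectories = FALSE)
  dat$trials$valid <- TRUE
  dat
}
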
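traj_from <- function(t, x, y) tibble::tibble(t_ms = t, x_mm = x, y_mm = y)

test_that("gap interpolation restores known signals and rejects bad gaps", {
  t <- seq(0, 400, by = 4)
  ## identity on gap-free input
  tr <- traj_from(t, sin(t / 50), cos(t / 50))
  expect_identical(interpolate_gaps(tr), tr)
  ## a missing interior point on a straight line is restored exactly
  tr2 <- traj_from(t, 2 * t + 1, -t)
  tr2$x_mm[20] <- NA
  tr2$y_mm[20] <- NA
  out <- interpolate_gaps(tr2)
  expect_equal(out$x_mm[20], 2 * t[20] + 1, tolerance = 1e-8)
  expect_equal(out$y_mm[20], -t[20], tolerance = 1e-8)
  ## a sampled cubic polynomial is restored to near machine precision
  cubic <- 1e-4 * t^3 - 0.02 * t^2 + 3 * t - 7
  tr3 <- traj_from(t, cubic, cubic)
  tr3$x_mm[c(40, 41)] <- NA
  out3 <- interpolate_gaps(tr3)
  expect_equal(out3$x_mm[40:41], cubic[40:41], tolerance = 1e-6)
  ## valid samples are untouched
  expect_identical(out3$x_mm[-c(40, 41)], cubic[-c(40, 41)])
  ## gap longer than max_gap
  tr4 <- traj_from(t, cubic, cubic)
  tr4$x_mm[30:45] <- NA
  expect_error(interpolate_gaps(tr4, max_gap = 50),
               class = "tojshift_not_interpolatable")
  ## gap at the end of the recording
  tr5 <- traj_from(t, cubic, cubic)
  tr5$x_mm[length(t)] <- NA
  expect_error(interpolate_gaps(tr5),
               class = "tojshift_not_interpolatable")
})

test_that("the zero-phase low-pass passes DC and attenuates per |H|^2", {
  cfg <- kinematics_config()
  t <- seq(0, 2000, by = 4)  # 250 Hz input
  ## constant position unchanged
  tr <- traj_from(t, rep(12.5, length(t)), rep(-3, length(t)))
  out <- resample_and_filter(tr, cfg)
  expect_equal(out$x_mm, rep(12.5, nrow(out)), tolerance = 1e-5)
  ## 50 Hz sinusoid: forward-backward 2nd-order Butterworth attenuates by
  ## the squared single-pass magnitude 1 / (1 + (50/6)^4)
  t1k <- seq(0, 2000, by = 1)
  s <- sin(2 * pi * 50 * t1k / 1000)
  trs <- traj_from(t1k, s, 0 * s)
  outs <- resample_and_filter(trs, cfg)
  mid <- outs$t_ms > 500 & outs$t_ms < 1500
  gain <- max(abs(outs$x_mm[mid]))
  expect_equal(gain, 1 / (1 + (50 / 6)^4), tolerance = 0.05)
  ## a slow reach passes nearly unchanged
  spec <- hand_trajectory_spec(c(0, 400), c(0, 100), 500, 800)
  tr_mj <- sample_trajectory(spec, sampling_rate = 1000, t_end = 2000)
  names(tr_mj) <- sub("^x_mm$", "x_mm", names(tr_mj))
  out_mj <- resample_and_filter(tr_mj[c("t_ms", "x_mm", "y_mm")], cfg)
  cmp <- approx(tr_mj$t_ms, tr_mj$y_mm, xout = out_mj$t_ms)$y
  expect_lt(max(abs(out_mj$y_mm - cmp)), 1)
})

test_that("refiltering an already filtered trajectory changes almost nothing", {
  cfg <- kinematics_config()
  spec <- hand_trajectory_spec(c(0, 400), c(0, 100), 500, 800)
  raw <- sample_trajectory(spec, sampling_rate = 250, t_end = 2000,
                           noise_sd = 0.5)
  raw <- interpolate_gaps(raw[c("t_ms", "x_mm", "y_mm")])
  once <- resample_and_filter(raw, cfg)
  twice <- resample_and_filter(once, cfg)
  expect_identical(once$t_ms, twice$t_ms)
  d_first <- max(abs(once$y_mm - approx(raw$t_ms, raw$y_mm,
                                        xout = once$t_ms)$y))
  d_second <- max(abs(twice$y_mm - once$y_mm))
  expect_lt(d_second, d_first / 5)
  expect_lt(d_second, 0.5)
})

test_that("onset/offset detection matches the analytic threshold crossings", {
  spec <- hand_trajectory_spec(c(0, 400), c(0, 100), 1000, 500)
  tr <- sample_trajectory(spec, sampling_rate = 1000, t_end = 2000)
  b <- detect_onset_offset(tr[c("t_ms", "x_mm", "y_mm")], 0.05)
  ## oracle: solve speed(t) = 0.05 on the closed-form quintic profile
  f <- function(t) min_jerk_speed(t, spec) - 0.05
  on_true <- uniroot(f, c(1000, 1250))$root
  off_true <- uniroot(f, c(1250, 1500))$root
  expect_lt(abs(b$onset - on_true), 2)
  expect_lt(abs(b$offset - off_true), 2)
  expect_lt(b$onset, 1250)           # onset < peak speed time
  expect_gt(b$offset, 1250)
  ## doubling the threshold never decreases onset nor increases offset
  b2 <- detect_onset_offset(tr[c("t_ms", "x_mm", "y_mm")], 0.10)
  expect_gte(b2$onset, b$onset)
  expect_lte(b2$offset, b$offset)
})

test_that("stationary and multi-burst trajectories are flagged", {
  t <- seq(0, 1000, by = 4)
  still <- traj_from(t, rep(0, length(t)), rep(0, length(t)))
  expect_error(detect_onset_offset(still), class = "tojshift_no_movement")
  ## two movement episodes separated by a long rest
  s1 <- hand_trajectory_spec(c(0, 400), c(0, 250), 100, 300)
  s2 <- hand_trajectory_spec(c(0, 250), c(0, 100), 700, 300)
  two <- traj_from(t,
                   rep(0, length(t)),
                   min_jerk_position(t, s1)[, 2] +
                     min_jerk_position(t, s2)[, 2] - 250)
  expect_error(detect_onset_offset(two), class = "tojshift_non_smooth")
})

test_that("postural change is the interpolated lateral crossing", {
  t <- seq(0, 400, by = 4)
  left <- traj_from(t, seq(100, -100, length.out = length(t)), t * 0)
  right <- traj_from(t, seq(-100, 100, length.out = length(t)), t * 0)
  expect_equal(detect_postural_change(left, right), 200, tolerance = 1e-6)
  ## no sign change -> NA
  expect_true(is.na(detect_postural_change(
    traj_from(t, rep(-100, length(t)), t * 0),
    traj_from(t, rep(100, length(t)), t * 0))))
})

test_that("detected crossing matches the generator's ground truth", {
  cfg <- sim_config(n_participants = 1, trials_per_condition = 3,
                    conditions = data.frame(start_posture = "uncrossed",
                                            end_posture = "crossed"),
                    traj_noise_sd = 0.2, seed = 13)
  dat <- generate_dataset(cfg, include_trajectories = TRUE)
  pre <- preprocess_trajectories(dat$trials, dat$trajectories)
  done <- pre$trials[pre$trials$valid, ]
  expect_gt(nrow(done), 0)
  expect_true(all(abs(done$postural_change_ms -
                        dat$trials$postural_change_ms[pre$trials$valid]) < 5))
})

test_that("exclusion rules fire one reason each and partition the trials", {
  cfg <- kinematics_config()
  good <- list(onset = 300, offset = 800)
  t0 <- make_trials(n = 1)
  expect_identical(apply_exclusions(t0, good, good, cfg)$reason, "valid")
  ## duration too short
  expect_identical(
    apply_exclusions(t0, list(onset = 300, offset = 450),
                     list(onset = 300, offset = 450), cfg)$reason,
    "duration")
  ## asynchronous onsets
  expect_identical(
    apply_exclusions(t0, list(onset = 100, offset = 600),
                     list(onset = 400, offset = 900), cfg)$reason,
    "asynchrony")
  ## missing localization response
  t_nr <- t0
  t_nr$reported_x_mm <- NA_real_
  expect_identical(apply_exclusions(t_nr, good, good, cfg)$reason, "response")
  ## upstream flags
  expect_identical(
    apply_exclusions(t0, NULL, NULL, cfg, interpolation_failed = TRUE)$reason,
    "interpolation")
  expect_identical(
    apply_exclusions(t0, NULL, NULL, cfg, non_smooth = TRUE)$reason,
    "smoothness")
})

test_that("default-noise generator output passes preprocessing almost fully", {
  cfg <- sim_config(n_participants = 1, trials_per_condition = 15,
                    conditions = data.frame(start_posture = "uncrossed",
                                            end_posture = "uncrossed"),
                    seed = 17)
  dat <- generate_dataset(cfg, include_trajectories = TRUE)
  pre <- preprocess_trajectories(dat$trials, dat$trajectories)
  expect_lt(mean(!pre$trials$valid), 0.01)
  reasons <- unique(pre$trials$exclusion_reason)
  expect_true(all(reasons %in% c("valid", "interpolation", "response",
                                 "duration", "asynchrony", "smoothness")))
  ## an impossible duration window excludes everything
  strict <- kinematics_config(min_duration = 50, max_duration = 150)
  pre2 <- preprocess_trajectories(dat$trials, dat$trajectories, strict)
  expect_true(all(!pre2$trials$valid))
  expect_true(all(pre2$trials$exclusion_reason == "duration"))
})
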
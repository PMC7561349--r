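test_that("dataset size follows the design and generation is deterministic", {
  dat1 <- quick_dataset(n_participants = 3, trials_per_condition = 10,
                        conditions = data.frame(
                          start_posture = c("uncrossed", "crossed"),
                          end_posture = c("uncrossed", "crossed")),
                        seed = 7)
  expect_equal(nrow(dat1$trials), 3 * 2 * 1 * 10)
  dat2 <- quick_dataset(n_participants = 3, trials_per_condition = 10,
                        conditions = data.frame(
                          start_posture = c("uncrossed", "crossed"),
                          end_posture = c("uncrossed", "crossed")),
                        seed = 7)
  expect_identical(dat1$trials, dat2$trials)
  ## first-stimulated hand balanced within each cell
  counts <- table(dat1$trials$participant_id, dat1$trials$start_posture,
                  dat1$trials$first_hand)
  expect_true(all(counts == 5))
})

test_that("the logistic choice model saturates and is symmetric at zero", {
  set.seed(1)
  fh <- rep(c("left", "right"), 500)
  always <- choose_response_hand(fh, crossed = FALSE, soa = 110,
                                 params = c(beta0 = Inf, beta_soa = 0,
                                            beta_cross = 0))
  expect_identical(always, fh)
  coin <- choose_response_hand(rep(fh, 10), crossed = FALSE, soa = 110,
                               params = c(beta0 = 0, beta_soa = 0,
                                          beta_cross = 0))
  p <- mean(coin == rep(fh, 10))
  expect_gt(p, 0.47)
  expect_lt(p, 0.53)
})

test_that("default choice parameters give > 15% errors even uncrossed", {
  set.seed(2)
  fh <- rep(c("left", "right"), 5000)
  resp <- choose_response_hand(fh, crossed = FALSE, soa = 110)
  err_unc <- mean(resp != fh)
  expect_gt(err_unc, 0.15)
  resp_c <- choose_response_hand(fh, crossed = TRUE, soa = 110)
  expect_gt(mean(resp_c != fh), err_unc)  # crossing penalty
  ## and accuracy grows with SOA
  resp_hi <- choose_response_hand(fh, crossed = FALSE, soa = 300)
  expect_gt(mean(resp_hi == fh), mean(resp == fh))
})

test_that("stimulus times span before, during and after the movement", {
  dat <- quick_dataset(n_participants = 2, trials_per_condition = 300,
                       conditions = data.frame(start_posture = "uncrossed",
                                               end_posture = "uncrossed"),
                       seed = 3)
  tr <- dat$trials
  onset <- (tr$onset_left_ms + tr$onset_right_ms) / 2
  offset <- (tr$offset_left_ms + tr$offset_right_ms) / 2
  frac <- c(before = mean(tr$t1_ms < onset),
            during = mean(tr$t1_ms >= onset & tr$t1_ms <= offset),
            after = mean(tr$t1_ms > offset))
  expect_true(all(frac > 0))
})

test_that("zero noise and forced-correct choices give exactly zero error", {
  dat <- quick_dataset(n_participants = 1, trials_per_condition = 50,
                       temporal_noise_sd = 0, temporal_bias = 0,
                       spatial_noise_sd = 0,
                       toj_choice_params = c(beta0 = Inf, beta_soa = 0,
                                             beta_cross = 0),
                       seed = 5)
  smp <- localization_samples(dat$trials, "time1", "correct")
  expect_equal(nrow(smp), nrow(dat$trials))
  expect_equal(smp$error, rep(0, nrow(smp)), tolerance = 1e-10)
})

test_that("time-reconstruction errors are positive early and negative late", {
  dat <- quick_dataset(n_participants = 1, trials_per_condition = 2500,
                       conditions = data.frame(start_posture = "uncrossed",
                                               end_posture = "uncrossed"),
                       temporal_noise_sd = 90, seed = 8)
  smp <- localization_samples(dat$trials, "time1", "correct")
  dur <- mean(smp$duration_ms)
  early <- smp$error[smp$t > 0 & smp$t < dur / 3]
  late <- smp$error[smp$t > 2 * dur / 3 & smp$t < dur]
  expect_gt(mean(early), 0)
  expect_lt(mean(late), 0)
})

test_that("space-to-limb reports hug the correct hand's path, others the chosen", {
  for (hyp in c("space_to_limb", "time_reconstruction", "stimulus_switch")) {
    dat <- quick_dataset(n_participants = 1, trials_per_condition = 150,
                         hypothesis = hyp, seed = 9)
    lat <- lateral_distance_test(dat$trials, n_perm = 500, seed = 1)
    expect_identical(lat$nearer,
                     if (hyp == "space_to_limb") "correct" else "chosen")
  }
})

test_that("unknown hypothesis labels are a config error", {
  dat <- quick_dataset(n_participants = 1, trials_per_condition = 5, seed = 1)
  expect_error(generate_localization(dat$trials, "teleportation"),
               class = "tojshift_config_error")
  expect_error(sim_config(hypothesis = "teleportation"))
})

test_that("sim config round-trips through the key-value file", {
  cfg <- exp2_config(seed = 42, temporal_bias = 5, gap_prob = 0.01)
  path <- withr::local_tempfile(fileext = ".txt")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2[setdiff(names(cfg2), "conditions")],
               cfg[setdiff(names(cfg), "conditions")])
  expect_equal(as.data.frame(cfg2$conditions), as.data.frame(cfg$conditions))
})
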
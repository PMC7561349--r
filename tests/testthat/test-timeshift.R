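test_that("sliding cost: a duplicated set is optimal at zero shift", {
  set.seed(41)
  cor <- synth_cell(30, sd_t = 40, sd_x = 3)
  cfg <- shift_config(shift_method = "sliding")
  cost0 <- common_curve_cost(cor, cor, 0, cfg)
  ## equals twice the correct-only residual around the (identical) curve
  kw <- cfg$curve$kernel_width
  v <- oracle_curve_at(cor$t, cor$t, cor$error, kw)
  expect_equal(as.numeric(cost0), 2 * sum((cor$error - v)^2),
               tolerance = 1e-9)
  for (s in c(-120, -30, 45, 200)) {
    expect_gte(as.numeric(common_curve_cost(cor, cor, s, cfg)),
               as.numeric(cost0))
  }
})

test_that("sliding cost of two constant-error sets is zero at every shift", {
  cor <- synth_cell(25)
  cor$error <- 4
  inc <- synth_cell(15)
  inc$error <- 4
  cfg <- shift_config(shift_method = "sliding")
  costs <- common_curve_cost(cor, inc, c(-200, -50, 0, 50, 200), cfg)
  expect_equal(as.numeric(costs), rep(0, 5), tolerance = 1e-12)
  ## ... which also exercises the smallest-|s| tie-break
  est <- estimate_time_shift(cor, inc, cfg)
  expect_equal(est$shift, 0)
})

test_that("both cost methods agree with naive from-scratch oracles", {
  set.seed(43)
  shifts <- seq(-300, 300, by = 25)
  for (i in 1:3) {
    cor <- synth_cell(20 + i, sd_t = 60, sd_x = 5)
    inc <- synth_cell(12 + i, sd_t = 60, sd_x = 5)
    for (method in c("reference", "sliding")) {
      cfg <- shift_config(shift_method = method)
      prod <- as.numeric(common_curve_cost(cor, inc, shifts, cfg))
      ora <- if (method == "reference") {
        oracle_profile_reference(cor, inc, shifts, cfg)
      } else {
        oracle_profile_sliding(cor, inc, shifts, cfg)
      }
      expect_equal(prod, ora, tolerance = 1e-10)
    }
  }
})

test_that("displaced copies are recovered at minus the displacement", {
  set.seed(47)
  ## sliding: displace the sample times of a smooth noiseless curve
  t <- runif(60, -200, 550)
  cor <- synth_cell(60)
  cor$t <- t
  cor$error <- 20 * sin(t / 120)
  for (delta in c(-100, 50)) {
    inc <- cor
    inc$t <- inc$t + delta
    est <- estimate_time_shift(cor, inc,
                               shift_config(shift_method = "sliding"))
    expect_lte(abs(est$shift + delta), 1)
  }
  ## reference: displace the aim time of the generating process
  cor2 <- synth_cell(60, aim_offset = 0)
  for (delta in c(-80, 120)) {
    inc2 <- synth_cell(40, aim_offset = delta)
    est2 <- estimate_time_shift(cor2, inc2, shift_config())
    expect_lte(abs(est2$shift + delta), 1)
  }
})

test_that("an exact copy self-aligns at zero under the reference method", {
  ## noiseless: the cost is exactly zero at s = 0 and positive elsewhere
  set.seed(53)
  cor <- synth_cell(50)
  est <- estimate_time_shift(cor, cor, shift_config())
  expect_equal(est$shift, 0)
  expect_equal(min(est$cost_profile), 0, tolerance = 1e-12)
  ## with sampling noise the minimum stays within a couple of ms
  cor2 <- synth_cell(120, sd_t = 50, sd_x = 4)
  est2 <- estimate_time_shift(cor2, cor2, shift_config())
  expect_lte(abs(est2$shift), 3)
})

test_that("estimates below the incorrect-trial floor are marked invalid", {
  set.seed(59)
  cor <- synth_cell(40, sd_t = 50)
  inc <- synth_cell(3, sd_t = 50)
  est <- estimate_time_shift(cor, inc, shift_config())
  expect_false(est$valid)
  expect_true(is.finite(est$shift))
  est2 <- estimate_time_shift(cor, synth_cell(8, sd_t = 50), shift_config())
  expect_true(est2$valid)
})

test_that("the shift table covers every cell and flags missing estimates", {
  dat <- quick_dataset(n_participants = 2, trials_per_condition = 60,
                       seed = 61)
  tab <- shift_table(dat$trials)
  expect_equal(nrow(tab), 2 * 4 * 2)  # participants x conditions x references
  expect_true(all(is.na(tab$shift_ms[!tab$valid])))
  ## spot-check one cell against a manual estimate
  cell <- dat$trials[dat$trials$participant_id == "P01" &
                       dat$trials$start_posture == "uncrossed" &
                       dat$trials$end_posture == "uncrossed", ]
  man <- estimate_time_shift(
    localization_samples(cell, "time1", "correct"),
    localization_samples(cell, "time1", "incorrect"),
    shift_config())
  got <- tab$shift_ms[tab$participant_id == "P01" &
                        tab$start_posture == "uncrossed" &
                        tab$end_posture == "uncrossed" &
                        tab$reference == "time1"]
  if (man$valid) expect_equal(got, man$shift) else expect_true(is.na(got))
  ## a dataset without incorrect trials yields an all-missing table
  perfect <- quick_dataset(n_participants = 2, trials_per_condition = 10,
                           toj_choice_params = c(beta0 = Inf, beta_soa = 0,
                                                 beta_cross = 0),
                           seed = 67)
  tab2 <- shift_table(perfect$trials)
  expect_true(all(!tab2$valid))
})

test_that("the participant bootstrap behaves at its degenerate points", {
  tab <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:6), each = 2),
    reference = "time1",
    shift_ms = 5,
    valid = TRUE)
  out <- bootstrap_shift_test(tab, "time1", h0 = 5, seed = 1)
  expect_equal(out$p_value, 1)
  expect_equal(unname(out$ci), c(5, 5))
  ## symmetric participant means keep zero inside the interval
  tab2 <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:9),
    reference = "time1",
    shift_ms = rep(c(-10, 0, 10), 3),
    valid = TRUE)
  out2 <- bootstrap_shift_test(tab2, "time1", h0 = 0, seed = 1)
  expect_lte(out2$ci[1], 0)
  expect_gte(out2$ci[2], 0)
  expect_gt(out2$p_value, 0.05)
  ## deterministic given the seed
  out3 <- bootstrap_shift_test(tab2, "time1", h0 = 0, seed = 1)
  expect_identical(out2, out3)
  expect_error(bootstrap_shift_test(tab2[0, ], "time1"),
               class = "tojshift_no_data")
})

test_that("hypothesis classification matches the statistic's signatures", {
  ## reference-method signatures
  expect_identical(classify_hypothesis(0, -110, 110), "time_reconstruction")
  expect_identical(classify_hypothesis(-110, -220, 110), "stimulus_switch")
  expect_identical(classify_hypothesis(-95, -178, 110), "stimulus_switch")
  ## sliding-method signatures follow the curve-translation picture
  expect_identical(classify_hypothesis(0, -110, 110, method = "sliding"),
                   "time_reconstruction")
  expect_identical(classify_hypothesis(110, 0, 110, method = "sliding"),
                   "stimulus_switch")
  expect_identical(classify_hypothesis(55, -55, 110, method = "sliding"),
                   "ambiguous")
  expect_identical(classify_hypothesis(NA, -110, 110), "unclassifiable")
})

test_that("the estimator's profile matches single-shift cost calls", {
  set.seed(71)
  cor <- synth_cell(30, sd_t = 60, sd_x = 5)
  inc <- synth_cell(12, sd_t = 60, sd_x = 5)
  cfg <- shift_config()
  est <- estimate_time_shift(cor, inc, cfg)
  for (s in c(-250, -60, 0, 90)) {
    expect_equal(est$cost_profile[match(s, est$shifts)],
                 as.numeric(common_curve_cost(cor, inc, s, cfg)),
                 tolerance = 1e-12)
  }
})
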
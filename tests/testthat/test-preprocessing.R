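test_that("3-SD exclusion flags exactly the arithmetic outliers", {
  # degenerate SD: nothing excluded
  t <- make_trials(list(list(run = "training", block = 1, rt = 400)))
  f <- flag_rt_outliers(t)
  expect_false(any(f$excluded))

  # 47 x 400 ms + one 5000 ms: bounds approx 495.8 +/- 3 * 663.9, so only
  # the 5000 ms trial falls outside
  rt <- c(rep(400, 47), 5000)
  t <- make_trials(list(list(run = "training", block = 1, rt = rt)))
  f <- flag_rt_outliers(t)
  tb <- f[run == "training"]
  expect_equal(which(tb$excluded), 48L)
  expect_equal(sum(f$excluded), 1L)

  expect_error(flag_rt_outliers(t, k = 0), "positive")
  expect_error(flag_rt_outliers(t, k = -2), "positive")
})

test_that("exclusion is idempotent and invariant to RT rescaling", {
  sim <- simulate_cohort(cohort_config(1L, 2L, seed = 31L))
  f1 <- flag_rt_outliers(sim$trials)
  f2 <- flag_rt_outliers(f1)
  expect_identical(f1$excluded, f2$excluded)

  scaled <- data.table::copy(sim$trials)
  scaled[participant_id == scaled$participant_id[1], rt_ms := rt_ms * 3.7]
  fs <- flag_rt_outliers(scaled)
  expect_identical(f1$excluded, fs$excluded)
})

test_that("default contamination produces exclusion rates of the expected order", {
  sim <- simulate_cohort(cohort_config(1L, 32L, seed = 41L))
  rate <- exclusion_rates(flag_rt_outliers(sim$trials))$cohort_mean_pct
  expect_gt(rate, 1)
  expect_lt(rate, 3)

  gp <- default_group_params()
  gp$outlier_rate_mean <- rep(0.02, 4)
  sim2 <- simulate_cohort(cohort_config(1L, 32L, group_params = gp, seed = 42L))
  rate2 <- exclusion_rates(flag_rt_outliers(sim2$trials))$cohort_mean_pct
  expect_gt(rate2, 1)
  expect_lt(rate2, 3)
})

test_that("block summaries average correct included trials only", {
  t <- make_trials(list(list(run = "training", block = 1, rt = 500)))
  b <- summarize_blocks(flag_rt_outliers(t))
  tb <- b[run == "training"]
  expect_equal(tb$mean_rt_correct, 500)
  expect_equal(tb$accuracy_pct, 100)
  expect_equal(tb$n_included, 48L)

  t <- make_trials(list(list(run = "training", block = 1, rt = 500,
                             correct = c(rep(TRUE, 46), FALSE, FALSE))))
  b <- summarize_blocks(flag_rt_outliers(t))
  expect_equal(b[run == "training"]$accuracy_pct, 100 * 46 / 48)

  t <- make_trials(list(list(run = "training", block = 1, rt = 500,
                             correct = FALSE)))
  b <- summarize_blocks(flag_rt_outliers(t))
  expect_equal(b[run == "training"]$accuracy_pct, 0)
  expect_true(is.na(b[run == "training"]$mean_rt_correct))
})

test_that("baseline normalization divides by the pre-random mean", {
  t <- make_trials(list(list(run = "training", block = 1, rt = 450)),
                   pre_rt = c(500, 520, 480, 500))
  b <- baseline_normalize(summarize_blocks(flag_rt_outliers(t)))
  expect_equal(b[run == "training"]$norm_rt, 450 / 500)
  expect_equal(mean(b[run == "pre_random"]$norm_rt), 1)

  raw <- baseline_normalize(summarize_blocks(flag_rt_outliers(t)),
                            raw_mode = TRUE)
  expect_equal(raw$norm_rt, raw$mean_rt_correct)
  expect_equal(raw$norm_acc, raw$accuracy_pct)
})

test_that("normalization is invariant to rescaling raw RTs; accuracy untouched", {
  sim <- simulate_cohort(cohort_config(1L, 2L, seed = 51L))
  b1 <- baseline_normalize(summarize_blocks(flag_rt_outliers(sim$trials)))
  scaled <- data.table::copy(sim$trials)
  scaled[, rt_ms := rt_ms * 2.5]
  b2 <- baseline_normalize(summarize_blocks(flag_rt_outliers(scaled)))
  expect_equal(b1$norm_rt, b2$norm_rt, tolerance = 1e-12)
  expect_equal(b1$accuracy_pct, b2$accuracy_pct)
})

test_that("participants without a usable baseline are dropped with a reason", {
  sim <- simulate_cohort(cohort_config(1L, 2L, seed = 61L))
  t <- data.table::as.data.table(sim$trials)
  victim <- t$participant_id[1]
  t <- t[!(participant_id == victim & run == "pre_random" & block == 4L)]
  b <- summarize_blocks(flag_rt_outliers(t))
  expect_message(nb <- baseline_normalize(b), "dropped")
  expect_false(victim %in% nb$participant_id)
  expect_equal(attr(nb, "dropped_participants"), victim)
})
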
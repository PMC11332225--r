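test_that("micro gains follow the first/last-repetition definitions", {
  r <- data.table::data.table(
    participant_id = "P1", session = 1L, run = "training",
    block = rep(1:16, each = 6L), repetition = rep(1:6, 16L),
    norm_rt = 1)
  r[block == 1L & repetition == 1L, norm_rt := 1.2]
  r[block == 1L & repetition == 6L, norm_rt := 1.0]
  r[block == 2L & repetition == 1L, norm_rt := 0.9]
  g <- micro_gains(r)
  expect_equal(g[measure == "micro_online" & index == 1L, gain], 0.2)
  expect_equal(g[measure == "micro_offline" & index == 1L, gain], 0.1)
  # constant means elsewhere: zero gains
  expect_true(all(g[measure == "micro_online" & index > 2L, gain] == 0))
})

test_that("micro gains telescope to first-minus-last repetition", {
  gp <- default_group_params()
  gp$acc_p_mean <- rep(1, 4)  # keep every window populated
  sim <- simulate_cohort(cohort_config(1L, 3L, group_params = gp, seed = 71L))
  res <- run_through_measures(sim)
  reps <- repetition_means(res$trials, res$blocks)
  micro <- attr(res$measures, "micro")
  for (pid in unique(micro$participant_id)) {
    m <- micro[participant_id == pid]
    if (anyNA(m$gain)) next
    r <- reps[participant_id == pid & run == "training"]
    lhs <- sum(m$gain)
    rhs <- r[block == 1L & repetition == 1L, norm_rt] -
      r[block == 16L & repetition == 6L, norm_rt]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("repetition means use correct included presses only", {
  t <- make_trials(list(list(run = "training", block = 1, rt = 450,
                             correct = rep(c(TRUE, FALSE), each = 4L))))
  res <- run_through_measures(list(trials = t))
  reps <- repetition_means(res$trials, res$blocks)
  # each window: 4 correct at 450, 4 incorrect -> mean over correct only
  expect_equal(unique(reps$norm_rt), 450 / 500)
})

test_that("learning magnitude is (random - sequential) / random", {
  t <- make_trials(list(
    list(run = "post_test", block = 1, rt = 400),
    list(run = "post_test", block = 2, rt = 400),
    list(run = "post_test", block = 3, rt = 400),
    list(run = "post_test", block = 4, rt = 400),
    list(run = "post_random", block = 1, rt = 500),
    list(run = "post_random", block = 2, rt = 500),
    list(run = "post_random", block = 3, rt = 500),
    list(run = "post_random", block = 4, rt = 500)))
  b <- baseline_normalize(summarize_blocks(flag_rt_outliers(t)))
  lm1 <- learning_magnitude(b, 1L)
  expect_equal(lm1$lm, (1.0 - 0.8) / 1.0)

  # no sequence advantage -> 0
  t2 <- make_trials(list(
    list(run = "post_test", block = 1, rt = 500),
    list(run = "post_test", block = 2, rt = 500),
    list(run = "post_test", block = 3, rt = 500),
    list(run = "post_test", block = 4, rt = 500),
    list(run = "post_random", block = 1, rt = 500),
    list(run = "post_random", block = 2, rt = 500),
    list(run = "post_random", block = 3, rt = 500),
    list(run = "post_random", block = 4, rt = 500)))
  b2 <- baseline_normalize(summarize_blocks(flag_rt_outliers(t2)))
  expect_equal(learning_magnitude(b2, 1L)$lm, 0)
})

test_that("macro-offline gains are test minus retest (positive = faster)", {
  mk <- function(rt_post, rt_retest) {
    extra <- c(
      lapply(1:4, function(b) list(run = "post_test", block = b, rt = rt_post)),
      lapply(1:4, function(b) list(run = "post_random", block = b, rt = 520)),
      lapply(1:4, function(b) list(run = "retest_seq", block = b,
                                   rt = rt_retest, session = 2L)),
      lapply(1:4, function(b) list(run = "retest_random", block = b, rt = 520,
                                   session = 2L)),
      lapply(1:4, function(b) list(run = "retest_seq", block = b,
                                   rt = rt_retest, session = 3L)),
      lapply(1:4, function(b) list(run = "retest_random", block = b, rt = 520,
                                   session = 3L)))
    make_trials(extra, pre_rt = rep(500, 4))
  }
  b <- baseline_normalize(summarize_blocks(flag_rt_outliers(mk(400, 350))))
  g <- macro_offline_gains(b)
  expect_equal(g$macro_seq_5h, 0.8 - 0.7)
  expect_equal(g$macro_seq_24h, 0.8 - 0.7)
  expect_equal(g$macro_rand_5h, 0)

  b2 <- baseline_normalize(summarize_blocks(flag_rt_outliers(mk(400, 400))))
  expect_equal(macro_offline_gains(b2)$macro_seq_24h, 0)
})

test_that("offline learning-magnitude change is the simple difference", {
  d <- offline_lm_change(0.1, 0.15, 0.08)
  expect_equal(d$d_lm_5h, 0.05)
  expect_equal(d$d_lm_24h, -0.02)
})

test_that("noise-free pipeline recovers generator closed forms to 1e-9", {
  sim <- simulate_cohort(cohort_config(2L, 1L, group_params = noise_free_params(),
                                       seed = 81L))
  res <- run_through_measures(sim)
  for (i in seq_len(nrow(sim$ground_truth))) {
    gt <- sim$ground_truth[i]
    em <- expected_measures(gt, 2L)
    m <- res$measures[participant_id == gt$participant_id]
    expect_equal(m$lm, em$lm, tolerance = 1e-9)
    expect_equal(m$lm_5h, em$lm_5h, tolerance = 1e-9)
    expect_equal(m$lm_24h, em$lm_24h, tolerance = 1e-9)
    expect_equal(m$macro_seq_5h, em$macro_seq_5h, tolerance = 1e-9)
    expect_equal(m$macro_seq_24h, em$macro_seq_24h, tolerance = 1e-9)
    expect_equal(m$macro_rand_5h, em$macro_rand_5h, tolerance = 1e-9)
    expect_equal(m$macro_rand_24h, em$macro_rand_24h, tolerance = 1e-9)
  }
})

test_that("all derived measures are invariant to rescaling raw RTs", {
  sim <- simulate_cohort(cohort_config(2L, 1L, seed = 91L))
  res1 <- run_through_measures(sim)
  scaled <- list(trials = data.table::copy(sim$trials))
  scaled$trials[, rt_ms := rt_ms * 4.2]
  res2 <- run_through_measures(scaled)
  cols <- setdiff(names(res1$measures), c("participant_id", "group", "age"))
  for (col in cols) {
    expect_equal(res1$measures[[col]], res2$measures[[col]], tolerance = 1e-12)
  }
})

test_that("monotone improvement yields nonnegative micro and macro gains", {
  gp <- noise_free_params()
  gp$within_drift_mean <- 0
  gp$gain_5h_mean <- pmax(gp$gain_5h_mean, 0.01)
  gp$gain_24h_mean <- pmax(gp$gain_24h_mean, 0.02)
  sim <- simulate_cohort(cohort_config(2L, 1L, group_params = gp, seed = 101L))
  res <- run_through_measures(sim)
  micro <- attr(res$measures, "micro")
  expect_true(all(micro$gain >= -1e-12))
  expect_true(all(res$measures$macro_seq_5h >= -1e-12))
  expect_true(all(res$measures$macro_seq_24h >= -1e-12))
})
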
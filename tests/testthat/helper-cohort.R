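library(data.table)

# Group parameters with all between-participant variation, noise and
# contamination switched off (deterministic generator; perfect accuracy).
noise_free_params <- function() {
  gp <- default_group_params()
  for (col in grep("_sd$", names(gp), value = TRUE)) gp[[col]] <- 0
  gp$noise_sd_mean <- 0
  gp$outlier_rate_mean <- 0
  gp$acc_p_mean <- 1
  gp
}

# Group parameters with every group mean equalized (null cohort).
null_params <- function() {
  gp <- default_group_params()
  mean_cols <- grep("_mean$", names(gp), value = TRUE)
  for (col in mean_cols) gp[[col]] <- mean(gp[[col]])
  gp
}

# simulate -> exclusion flags -> block summaries -> normalization -> measures
run_through_measures <- function(sim, k = 3, raw_mode = FALSE) {
  trials <- flag_rt_outliers(sim$trials, k = k)
  blocks <- baseline_normalize(summarize_blocks(trials), raw_mode = raw_mode)
  measures <- derive_measures(trials, blocks, raw_mode = raw_mode)
  list(trials = trials, blocks = blocks, measures = measures)
}

# Minimal hand-built trial table: one participant, 4 pre_random blocks of
# constant RT plus caller-supplied extra blocks. `extra` is a list of lists
# with fields run, block, rt (length 48 or scalar), correct (length 48 or
# scalar), session.
make_trials <- function(extra = list(), pre_rt = c(500, 520, 480, 500),
                        pid = "P1", group = "YA", age = 25) {
  mk_block <- function(run, block, rt, correct, session, variant) {
    target <- if (variant == "sequential") rep(srtt_sequence(), 6L) else {
      set.seed(block * 7L + session)
      sequence_order("pseudorandom", 48L)
    }
    correct <- rep(correct, length.out = 48L)
    response <- ifelse(correct, target, ((target + 1L - 1L) %% 8L) + 1L)
    data.table(
      participant_id = pid, group = group, age = age, experiment = 1L,
      session = session, run = run, block = block, trial = 1:48,
      target = target, response = as.integer(response), correct = correct,
      rt_ms = rep(rt, length.out = 48L),
      repetition = as.integer(ceiling((1:48) / 8))
    )
  }
  pre <- rbindlist(lapply(1:4, function(b) {
    mk_block("pre_random", b, pre_rt[b], TRUE, 1L, "pseudorandom")
  }))
  rest <- rbindlist(lapply(extra, function(e) {
    mk_block(e$run, e$block, e$rt, e$correct %||% TRUE, e$session %||% 1L,
             if (e$run %in% c("training", "post_test", "retest_seq"))
               "sequential" else "pseudorandom")
  }))
  rbind(pre, rest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
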
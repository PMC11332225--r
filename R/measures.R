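#' Per-repetition normalized RT means in sequential runs
#'
#' Divides each trial's RT by the participant's pre-learning random baseline
#' (mean of the 4 pre_random block mean RTs) and averages over the included
#' correct keypresses of each 8-press sequence repetition within a block.
#' Windows with no included correct press yield a missing mean.
#'
#' @param trials Trial table with exclusion flags.
#' @param blocks Normalized block table from [baseline_normalize()] (source
#'   of the per-participant baseline).
#' @param raw_mode When TRUE, trial RTs are not divided by the baseline.
#' @return data.table: participant_id, session, run, block, repetition,
#'   norm_rt (mean normalized RT; NA if the window is empty).
#' @export
repetition_means <- function(trials, blocks, raw_mode = FALSE) {
  t <- data.table::as.data.table(trials)
  if (!"excluded" %in% names(t)) stop("run flag_rt_outliers() first")
  base <- unique(data.table::as.data.table(blocks)[, .(participant_id, baseline_rt)])
  t <- merge(t[run %in% .SEQ_RUNS], base, by = "participant_id", sort = FALSE)
  if (isTRUE(raw_mode)) t[, baseline_rt := 1]
  r <- t[, {
    keep <- !excluded & correct
    .(norm_rt = if (any(keep)) mean(rt_ms[keep] / baseline_rt[keep]) else NA_real_)
  }, by = .(participant_id, session, run, block, repetition)]
  data.table::setorder(r, participant_id, session, run, block, repetition)
  r[]
}

#' Micro-online and micro-offline gains across training
#'
#' For the 16 training blocks of session 1: micro-online gain of block n is
#' rep1(n) - rep6(n) (first minus last sequence repetition; positive =
#' within-block RT decrease), and the micro-offline gain of rest interval n
#' is rep6(n) - rep1(n+1) (change across the 15-s rest; positive =
#' improvement over rest). Missing repetition means propagate to the
#' corresponding entries.
#'
#' @param rep_means Output of [repetition_means()].
#' @return data.table with one row per participant and index: columns
#'   participant_id, index (block 1-16 for online, rest interval 1-15 for
#'   offline), measure ("micro_online"/"micro_offline"), gain.
#' @export
micro_gains <- function(rep_means) {
  r <- data.table::as.data.table(rep_means)
  tr <- r[session == 1L & run == "training"]
  out <- tr[, {
    stopifnot(max(block) <= 16L)
    rep1 <- rep(NA_real_, 16L); rep6 <- rep(NA_real_, 16L)
    rep1[block[repetition == 1L]] <- norm_rt[repetition == 1L]
    rep6[block[repetition == 6L]] <- norm_rt[repetition == 6L]
    online <- rep1 - rep6
    offline <- rep6[1:15] - rep1[2:16]
    .(index = c(1:16, 1:15),
      measure = rep(c("micro_online", "micro_offline"), c(16L, 15L)),
      gain = c(online, offline))
  }, by = participant_id]
  out[]
}

#' Sequence-specific learning magnitude
#'
#' lm = (Rbar - Sbar) / Rbar, where Sbar is the mean normalized RT of the
#' session's sequential test/retest blocks and Rbar the mean normalized RT
#' of the same session's random blocks (post_random in session 1,
#' retest_random in sessions 2-3). Positive values mean the sequential
#' variant is performed faster than the random one, i.e. sequence-specific
#' learning. Oriented so that larger = more learning for an RT outcome
#' (see the package vignette on sign conventions).
#'
#' @param blocks Normalized block table.
#' @param session 1, 2 or 3.
#' @return data.table: participant_id, lm (NA when a needed run is missing).
#' @export
learning_magnitude <- function(blocks, session = 1L) {
  b <- data.table::as.data.table(blocks)
  seq_run <- if (session == 1L) "post_test" else "retest_seq"
  ran_run <- if (session == 1L) "post_random" else "retest_random"
  s <- session
  wide <- b[session == s & run %in% c(seq_run, ran_run),
            .(m = mean(norm_rt), n = .N), by = .(participant_id, run)]
  out <- data.table::dcast(wide, participant_id ~ run, value.var = "m")
  for (col in c(seq_run, ran_run)) {
    if (!col %in% names(out)) out[, (col) := NA_real_]
  }
  out[, lm := (get(ran_run) - get(seq_run)) / get(ran_run)]
  out[, .(participant_id, lm)]
}

#' Macro-offline performance gains (5 h and 24 h)
#'
#' Sequential gain over offline period s: mean normalized RT of the session-1
#' post-learning test run minus the mean normalized RT of the session-s
#' sequential retest run; random-variant gains analogously use post_random
#' vs retest_random. Positive = faster (improved) at retest; this mirrors
#' the first-minus-last orientation of the micro gains. Missing sessions or
#' runs yield missing gains for those contrasts only.
#'
#' @param blocks Normalized block table (Experiment 2).
#' @return data.table: participant_id, macro_seq_5h, macro_seq_24h,
#'   macro_rand_5h, macro_rand_24h.
#' @export
macro_offline_gains <- function(blocks) {
  b <- data.table::as.data.table(blocks)
  m <- b[, .(m = mean(norm_rt)), by = .(participant_id, session, run)]
  m[, key := paste0("s", session, "_", run)]
  wide <- data.table::dcast(m, participant_id ~ key, value.var = "m")
  col <- function(nm) if (nm %in% names(wide)) wide[[nm]] else NA_real_
  data.table::data.table(
    participant_id = wide$participant_id,
    macro_seq_5h = col("s1_post_test") - col("s2_retest_seq"),
    macro_seq_24h = col("s1_post_test") - col("s3_retest_seq"),
    macro_rand_5h = col("s1_post_random") - col("s2_retest_random"),
    macro_rand_24h = col("s1_post_random") - col("s3_retest_random")
  )
}

#' Offline change in sequence-specific learning magnitude
#'
#' d_lm_s = lm at retest session s minus lm at session 1. Positive values
#' mean the sequence-specific advantage grew over the offline period.
#'
#' @param lm,lm_5h,lm_24h Learning magnitudes (vectors, aligned).
#' @return List with `d_lm_5h` and `d_lm_24h`.
#' @export
offline_lm_change <- function(lm, lm_5h, lm_24h) {
  list(d_lm_5h = lm_5h - lm, d_lm_24h = lm_24h - lm)
}

#' Derive all per-participant measures
#'
#' Convenience wrapper producing one row per participant: learning
#' magnitudes (session 1 and, for Experiment 2, the 5 h / 24 h retests and
#' their offline changes), mean micro-online and micro-offline gains, and
#' the macro-offline gains. The long-format micro table is attached as the
#' `micro` attribute.
#'
#' @param trials Trial table with exclusion flags.
#' @param blocks Normalized block table.
#' @param raw_mode Passed to [repetition_means()].
#' @return data.table keyed by participant_id.
#' @export
derive_measures <- function(trials, blocks, raw_mode = FALSE) {
  b <- data.table::as.data.table(blocks)
  experiment <- b$experiment[1L]
  reps <- repetition_means(trials, b, raw_mode = raw_mode)
  micro <- micro_gains(reps)
  micro_summary <- data.table::dcast(
    micro[, .(gain = mean(gain, na.rm = TRUE)), by = .(participant_id, measure)],
    participant_id ~ measure, value.var = "gain")
  out <- merge(b[, .(group = group[1L], age = age[1L]), by = participant_id],
               learning_magnitude(b, 1L), by = "participant_id", all.x = TRUE)
  out <- merge(out, micro_summary, by = "participant_id", all.x = TRUE)
  data.table::setnames(out, c("micro_online", "micro_offline"),
                       c("mean_micro_online", "mean_micro_offline"),
                       skip_absent = TRUE)
  if (identical(as.integer(experiment), 2L)) {
    lm5 <- learning_magnitude(b, 2L); data.table::setnames(lm5, "lm", "lm_5h")
    lm24 <- learning_magnitude(b, 3L); data.table::setnames(lm24, "lm", "lm_24h")
    out <- merge(out, lm5, by = "participant_id", all.x = TRUE)
    out <- merge(out, lm24, by = "participant_id", all.x = TRUE)
    d <- offline_lm_change(out$lm, out$lm_5h, out$lm_24h)
    out[, `:=`(d_lm_5h = d$d_lm_5h, d_lm_24h = d$d_lm_24h)]
    out <- merge(out, macro_offline_gains(b), by = "participant_id", all.x = TRUE)
  }
  data.table::setattr(out, "micro", micro)
  out[]
}
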
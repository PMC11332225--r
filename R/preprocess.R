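#' Flag trial-level reaction-time outliers
#'
#' For each (participant, session, run, block), computes the mean m and
#' standard deviation s over all 48 RTs of the block (correct and incorrect;
#' one pass, no iterative re-trimming) and flags trials with RT outside
#' [m - k s, m + k s] as excluded. A block of identical RTs (s = 0) excludes
#' nothing. The operation is idempotent: bounds are always computed from all
#' 48 trials, so re-running changes no flags.
#'
#' @param trials A trial table.
#' @param k Exclusion threshold in within-block SDs (default 3).
#' @return The trial table with a logical `excluded` column; attribute
#'   `exclusion_rates` holds the per-participant rates and the cohort mean
#'   (see [exclusion_rates()]).
#' @export
flag_rt_outliers <- function(trials, k = 3) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("`k` must be a single positive number")
  }
  if (anyNA(trials$rt_ms)) stop("rt_ms must be present for all rows")
  t <- data.table::as.data.table(trials)
  t[, excluded := {
    m <- mean(rt_ms)
    s <- sd(rt_ms)
    if (is.na(s) || s == 0) rep(FALSE, .N)
    else rt_ms < m - k * s | rt_ms > m + k * s
  }, by = .(participant_id, session, run, block)]
  rates <- t[, .(n_excluded = sum(excluded), n_total = .N,
                 rate_pct = 100 * mean(excluded)), by = participant_id]
  data.table::setattr(t, "exclusion_rates",
                      list(by_participant = rates,
                           cohort_mean_pct = mean(rates$rate_pct)))
  t[]
}

#' Per-participant and cohort trial-exclusion rates
#'
#' @param trials A trial table with an `excluded` flag (from
#'   [flag_rt_outliers()]).
#' @return List with `by_participant` (data.table of counts and percentage)
#'   and `cohort_mean_pct` (unweighted mean of participant percentages).
#' @export
exclusion_rates <- function(trials) {
  att <- attr(trials, "exclusion_rates")
  if (!is.null(att)) return(att)
  t <- data.table::as.data.table(trials)
  rates <- t[, .(n_excluded = sum(excluded), n_total = .N,
                 rate_pct = 100 * mean(excluded)), by = participant_id]
  list(by_participant = rates, cohort_mean_pct = mean(rates$rate_pct))
}

#' Summarize blocks: mean correct RT and accuracy
#'
#' Computes, per (participant, session, run, block), the mean RT over
#' included correct trials and the percentage of correct keypresses among
#' included trials. Blocks with no included correct trial yield a missing
#' mean (never 0). The familiarization block is dropped (not analyzed).
#'
#' @param trials A trial table with exclusion flags.
#' @return A data.table with one row per block: participant_id, group, age,
#'   experiment, session, run, block, mean_rt_correct, accuracy_pct,
#'   n_included, n_excluded.
#' @export
summarize_blocks <- function(trials) {
  t <- data.table::as.data.table(trials)
  if (!"excluded" %in% names(t)) stop("run flag_rt_outliers() first")
  t <- t[run != "familiarization"]
  b <- t[, {
    inc <- !excluded
    corr <- inc & correct
    .(group = group[1L], age = age[1L], experiment = experiment[1L],
      mean_rt_correct = if (any(corr)) mean(rt_ms[corr]) else NA_real_,
      accuracy_pct = if (any(inc)) 100 * sum(corr) / sum(inc) else NA_real_,
      n_included = sum(inc), n_excluded = sum(excluded))
  }, by = .(participant_id, session, run, block)]
  data.table::setcolorder(b, c("participant_id", "group", "age", "experiment",
                               "session", "run", "block"))
  b[]
}

#' Normalize block summaries to the pre-learning random baseline
#'
#' Divides each block's outcome by the participant's mean outcome across the
#' four pre-learning random blocks (session 1), for every run and session
#' including pre_random itself; applied to both speed and accuracy. With
#' `raw_mode = TRUE` the normalized fields pass the raw values through
#' unchanged (non-normalized sensitivity analyses). Participants lacking a
#' usable baseline (any of the 4 pre_random block means missing) are dropped
#' and reported in the `dropped_participants` attribute.
#'
#' @param blocks Output of [summarize_blocks()].
#' @param raw_mode Pass raw values through instead of normalizing.
#' @return The block table with `norm_rt` and `norm_acc` columns.
#' @export
baseline_normalize <- function(blocks, raw_mode = FALSE) {
  b <- data.table::as.data.table(blocks)
  base <- b[run == "pre_random" & session == 1L,
            .(baseline_rt = mean(mean_rt_correct),
              baseline_acc = mean(accuracy_pct),
              n_base = .N),
            by = participant_id]
  bad <- base[is.na(baseline_rt) | n_base != 4L, participant_id]
  no_base <- setdiff(unique(b$participant_id), base$participant_id)
  dropped <- union(bad, no_base)
  if (length(dropped)) {
    message(length(dropped), " participant(s) dropped: unusable pre-learning ",
            "random baseline (", paste(dropped, collapse = ", "), ")")
    b <- b[!participant_id %in% dropped]
  }
  b <- merge(b, base[!participant_id %in% dropped,
                     .(participant_id, baseline_rt, baseline_acc)],
             by = "participant_id", sort = FALSE)
  if (isTRUE(raw_mode)) {
    b[, `:=`(norm_rt = mean_rt_correct, norm_acc = accuracy_pct)]
  } else {
    b[, `:=`(norm_rt = mean_rt_correct / baseline_rt,
             norm_acc = accuracy_pct / baseline_acc)]
  }
  b[, `:=`(baseline_acc = NULL)]
  data.table::setattr(b, "dropped_participants", dropped)
  data.table::setorder(b, participant_id, session, run, block)
  b[]
}
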
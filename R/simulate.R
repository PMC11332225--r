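.sched_cache <- new.env(parent = emptyenv())

.AGE_RANGES <- data.frame(
  group = c("CH", "AD", "YA", "OA"),
  age_min = c(7, 13, 18, 55),
  age_max = c(12, 17, 35, 75),
  stringsAsFactors = FALSE
)

#' Default group-level generating parameters
#'
#' Group means (and between-participant SDs) for every ground-truth field of
#' the cohort generator. The values are fabricated: they are chosen to
#' reproduce the ordinal pattern reported across age groups -- slower
#' baselines in children and older adults, smaller sequence-specific learning
#' in children, larger micro rest-interval jumps in children, and macro
#' offline gains ordered children > adolescents > young adults > older adults
#' (with a small overnight loss in older adults) -- not any quantitative
#' empirical result. All fields are overridable through `group_params` in the
#' cohort configuration.
#'
#' @return A data.frame with one row per group (CH, AD, YA, OA) and columns
#'   `<field>_mean` / `<field>_sd` for each generating parameter.
#' @export
default_group_params <- function() {
  p <- data.frame(
    group = c("CH", "AD", "YA", "OA"),
    baseline_rt_mean = c(650, 480, 420, 550), baseline_rt_sd = c(60, 60, 60, 60),
    general_amp_mean = c(0.20, 0.15, 0.12, 0.14), general_amp_sd = rep(0.03, 4),
    general_rate_mean = rep(0.15, 4), general_rate_sd = rep(0, 4),
    seq_amp_mean = c(0.06, 0.10, 0.10, 0.09), seq_amp_sd = rep(0.02, 4),
    seq_rate_mean = rep(0.25, 4), seq_rate_sd = rep(0, 4),
    within_drift_mean = rep(0.004, 4), within_drift_sd = rep(0.002, 4),
    micro_jump_mean = c(0.012, 0.008, 0.008, 0.008), micro_jump_sd = rep(0.004, 4),
    gain_5h_mean = c(0.05, 0.04, 0.00, 0.00), gain_5h_sd = rep(0.04, 4),
    gain_24h_mean = c(0.12, 0.07, 0.05, -0.02), gain_24h_sd = rep(0.04, 4),
    acc_p_mean = c(0.92, 0.95, 0.96, 0.95), acc_p_sd = rep(0.02, 4),
    noise_sd_mean = rep(0.15, 4), noise_sd_sd = rep(0, 4),
    outlier_rate_mean = rep(0.015, 4), outlier_rate_sd = rep(0, 4),
    stringsAsFactors = FALSE
  )
  p$outlier_scale_lo <- 3
  p$outlier_scale_hi <- 8
  p
}

#' Build a cohort configuration
#'
#' @param experiment 1 or 2 (session structure; see [experiment_design()]).
#' @param n_per_group Participants per age group (>= 1).
#' @param group_params Group-level means/SDs as in [default_group_params()];
#'   NULL uses the defaults.
#' @param seed Master seed; the cohort is a pure function of
#'   (configuration, seed).
#' @param continuous_age When TRUE, the sequence-specific amplitude is a
#'   planted quadratic function of age (peak 0.10 at 24 years, curvature
#'   -3e-4 per year^2) instead of a group-mean draw, to exercise
#'   age-trajectory recovery.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(experiment = 2L, n_per_group = 27L,
                          group_params = NULL, seed = 1L,
                          continuous_age = FALSE) {
  if (n_per_group < 1) stop("`n_per_group` must be >= 1")
  experiment <- as.integer(experiment)
  if (!experiment %in% c(1L, 2L)) stop("`experiment` must be 1 or 2")
  gp <- if (is.null(group_params)) default_group_params() else group_params
  stopifnot(identical(sort(gp$group), sort(.GROUP_LEVELS)))
  structure(list(experiment = experiment, n_per_group = as.integer(n_per_group),
                 group_params = gp, seed = as.integer(seed),
                 continuous_age = isTRUE(continuous_age)),
            class = "cohort_config")
}

# Planted quadratic age trajectory of the sequence-specific amplitude,
# used in continuous-age mode (7-35 window): vertex at 24 years.
.SEQ_AMP_QUAD <- c(peak = 0.10, vertex = 24, curvature = -3e-4)

seq_amp_from_age <- function(age) {
  .SEQ_AMP_QUAD[["peak"]] +
    .SEQ_AMP_QUAD[["curvature"]] * (age - .SEQ_AMP_QUAD[["vertex"]])^2
}

.validate_gt <- function(gt) {
  with(as.list(gt), {
    if (!is.finite(baseline_rt) || baseline_rt <= 0) stop("baseline_rt must be > 0")
    if (acc_p <= 0 || acc_p > 1) stop("acc_p must be in (0,1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate must be in [0,1)")
    if (general_rate < 0 || seq_rate < 0) stop("rates must be >= 0")
  })
  invisible(TRUE)
}

#' Trial schedule for one participant
#'
#' Expands the experiment design into one row per keypress with the indices
#' the generator's mean model needs: `t_cum` (cumulative block index across
#' the whole experiment, familiarization = 1), `b_seq` (cumulative sequential
#' block index across training, post-test and retests; NA in pseudorandom
#' runs) and `rest_idx` (completed rest intervals within the run, i.e.
#' block-within-run - 1).
#'
#' @param experiment 1 or 2.
#' @return A data.table with columns session, run, variant, block, trial,
#'   repetition, t_cum, b_seq, rest_idx.
#' @export
participant_schedule <- function(experiment) {
  key <- as.character(experiment)
  cached <- .sched_cache[[key]]
  if (!is.null(cached)) return(data.table::copy(cached))
  des <- experiment_design(experiment)
  blocks <- des[rep(seq_len(nrow(des)), des$n_blocks), ]
  blocks$block <- unlist(lapply(des$n_blocks, seq_len))
  blocks$t_cum <- seq_len(nrow(blocks))
  is_seq <- blocks$variant == "sequential"
  blocks$b_seq <- NA_integer_
  blocks$b_seq[is_seq] <- seq_len(sum(is_seq))
  sched <- data.table::as.data.table(
    blocks[rep(seq_len(nrow(blocks)), each = .TRIALS_PER_BLOCK), ])
  sched[, trial := rep(1:48, length.out = .N)]
  sched[, repetition := as.integer(ceiling(trial / 8))]
  sched[, rest_idx := block - 1L]
  sched[, n_blocks := NULL]
  .sched_cache[[key]] <- sched
  data.table::copy(sched)
}

#' Expected log reaction time under the generator's mean model
#'
#' The deterministic component of the generator, exposed so tests and
#' analyses can compare pipeline output against closed-form expectations.
#' For a trial in cumulative block `t_cum`, sequential block `b_seq`,
#' repetition `r`, with `rest_idx` completed rest intervals in its run:
#'
#' log E RT = log(baseline_rt) - general_amp (1 - exp(-general_rate t))
#'   - [sequential] seq_amp (1 - exp(-seq_rate b)) + within_drift (r - 1)
#'   - micro_jump rest_idx - [session 2] gain_5h - [session 3] gain_24h
#'
#' @param gt One-row ground truth (list or data.frame row).
#' @param sched Schedule rows as from [participant_schedule()].
#' @return Numeric vector of expected log RT (log ms), one per schedule row.
#' @export
expected_log_rt <- function(gt, sched) {
  gt <- as.list(gt)
  is_seq <- sched$variant == "sequential"
  seq_term <- ifelse(is_seq,
                     gt$seq_amp * (1 - exp(-gt$seq_rate * ifelse(is.na(sched$b_seq), 0, sched$b_seq))),
                     0)
  log(gt$baseline_rt) -
    gt$general_amp * (1 - exp(-gt$general_rate * sched$t_cum)) -
    seq_term +
    gt$within_drift * (sched$repetition - 1L) -
    gt$micro_jump * sched$rest_idx -
    (sched$session == 2L) * gt$gain_5h -
    (sched$session == 3L) * gt$gain_24h
}

#' Simulate one participant's keypress table
#'
#' Observed RT is exp(expected log RT + Normal(0, noise_sd)); with
#' probability `outlier_rate` a trial's RT is further multiplied by a
#' Uniform(outlier_scale_lo, outlier_scale_hi) factor (attentional lapses /
#' task interruptions). Responses are correct with probability `acc_p`;
#' incorrect responses are drawn uniformly from the 7 non-target keys.
#'
#' @param gt One-row ground truth with fields participant_id, group, age,
#'   seed and the generating parameters (see [default_group_params()]).
#' @param experiment 1 or 2.
#' @return A trial table (data.table) with (1+4+16+4+4) * 48 = 1392 rows for
#'   Experiment 1 and 2160 for Experiment 2.
#' @export
simulate_participant <- function(gt, experiment) {
  gt <- as.list(gt)
  .validate_gt(gt)
  sched <- participant_schedule(experiment)
  n <- nrow(sched)
  set.seed(gt$seed)

  target <- integer(n)
  run_key <- paste(sched$session, sched$run)
  for (rk in unique(run_key)) {
    idx <- which(run_key == rk)
    variant <- sched$variant[idx[1L]]
    target[idx] <- sequence_order(variant, length(idx))
  }

  mu <- expected_log_rt(gt, sched)
  rt <- exp(mu + rnorm(n, 0, gt$noise_sd))
  is_outlier <- runif(n) < gt$outlier_rate
  n_out <- sum(is_outlier)
  if (n_out) {
    rt[is_outlier] <- rt[is_outlier] *
      runif(n_out, gt$outlier_scale_lo, gt$outlier_scale_hi)
  }
  correct <- runif(n) < gt$acc_p
  response <- target
  n_err <- sum(!correct)
  if (n_err) {
    response[!correct] <-
      ((target[!correct] - 1L + sample.int(7L, n_err, replace = TRUE)) %% 8L) + 1L
  }

  data.table::data.table(
    participant_id = as.character(gt$participant_id),
    group = as.character(gt$group),
    age = as.numeric(gt$age),
    experiment = as.integer(experiment),
    session = sched$session,
    run = sched$run,
    block = sched$block,
    trial = sched$trial,
    target = target,
    response = response,
    correct = correct,
    rt_ms = rt,
    repetition = sched$repetition
  )
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Simulate a full cohort with exportable ground truth
#'
#' Draws per-participant generating parameters from the group-level
#' distributions, assigns each participant a child seed derived
#' deterministically from the master seed, and simulates all keypresses.
#' Output is a pure function of the configuration and master seed.
#'
#' @param cfg A [cohort_config()].
#' @return List with `trials` (keypress-level data.table over all
#'   4 * n_per_group participants) and `ground_truth` (one row per
#'   participant with every generating parameter).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  gp <- cfg$group_params
  n <- cfg$n_per_group
  set.seed(cfg$seed)
  gt_list <- vector("list", 4L)
  for (gi in seq_len(4L)) {
    g <- .GROUP_LEVELS[gi]
    row <- gp[gp$group == g, ]
    ar <- .AGE_RANGES[.AGE_RANGES$group == g, ]
    draw <- function(field, lo = -Inf, hi = Inf) {
      .rtrunc_norm(n, row[[paste0(field, "_mean")]], row[[paste0(field, "_sd")]],
                   lo, hi)
    }
    age <- runif(n, ar$age_min, ar$age_max)
    seq_amp <- draw("seq_amp")
    if (cfg$continuous_age && g != "OA") {
      seq_amp <- seq_amp - row$seq_amp_mean + seq_amp_from_age(age)
    }
    gt_list[[gi]] <- data.table::data.table(
      participant_id = sprintf("%s%03d", g, seq_len(n)),
      group = g,
      age = age,
      baseline_rt = draw("baseline_rt", lo = 100),
      general_amp = draw("general_amp"),
      general_rate = draw("general_rate", lo = 0),
      seq_amp = seq_amp,
      seq_rate = draw("seq_rate", lo = 0),
      within_drift = draw("within_drift"),
      micro_jump = draw("micro_jump"),
      gain_5h = draw("gain_5h"),
      gain_24h = draw("gain_24h"),
      acc_p = draw("acc_p", lo = 0.5, hi = 1),
      noise_sd = draw("noise_sd", lo = 0),
      outlier_rate = draw("outlier_rate", lo = 0, hi = 0.99),
      outlier_scale_lo = row$outlier_scale_lo,
      outlier_scale_hi = row$outlier_scale_hi
    )
  }
  gt <- data.table::rbindlist(gt_list)
  gt[, seed := sample.int(.Machine$integer.max - 1L, .N)]
  trials <- data.table::rbindlist(
    lapply(seq_len(nrow(gt)), function(i) {
      simulate_participant(gt[i], cfg$experiment)
    })
  )
  list(trials = trials, ground_truth = gt)
}

#' Closed-form expected derived measures for one participant
#'
#' Evaluates the generator's deterministic mean model through the exact
#' arithmetic of the preprocessing and measures stages (block means of
#' expected RT, normalization by the pre-learning random baseline, learning
#' magnitudes, macro-offline gains). With noise_sd = 0, outlier_rate = 0 and
#' acc_p = 1, pipeline estimates equal these values to numerical precision;
#' with noise they are the target of parameter-recovery checks.
#'
#' @param gt One-row ground truth.
#' @param experiment 1 or 2.
#' @return List with `block_means` (expected raw block mean RT),
#'   `baseline`, `lm`, and for Experiment 2 `lm_5h`, `lm_24h`,
#'   `macro_seq_5h`, `macro_seq_24h`, `macro_rand_5h`, `macro_rand_24h`.
#' @export
expected_measures <- function(gt, experiment) {
  sched <- participant_schedule(experiment)
  sched[, exp_rt := exp(expected_log_rt(as.list(gt), sched))]
  bm <- sched[, .(mean_rt = mean(exp_rt)), by = .(session, run, block)]
  baseline <- bm[run == "pre_random", mean(mean_rt)]
  bm[, norm_rt := mean_rt / baseline]
  run_mean <- function(s, r) bm[session == s & run == r, mean(norm_rt)]
  lm_of <- function(sbar, rbar) (rbar - sbar) / rbar
  out <- list(
    block_means = bm,
    baseline = baseline,
    lm = lm_of(run_mean(1, "post_test"), run_mean(1, "post_random"))
  )
  if (experiment == 2L) {
    out$lm_5h <- lm_of(run_mean(2, "retest_seq"), run_mean(2, "retest_random"))
    out$lm_24h <- lm_of(run_mean(3, "retest_seq"), run_mean(3, "retest_random"))
    out$macro_seq_5h <- run_mean(1, "post_test") - run_mean(2, "retest_seq")
    out$macro_seq_24h <- run_mean(1, "post_test") - run_mean(3, "retest_seq")
    out$macro_rand_5h <- run_mean(1, "post_random") - run_mean(2, "retest_random")
    out$macro_rand_24h <- run_mean(1, "post_random") - run_mean(3, "retest_random")
  }
  out
}
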
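.trend_flag <- function(p) {
  if (is.na(p)) "" else if (p < 0.05) "*" else if (p < 0.1) "~ (trend)" else ""
}

# Long table of one value per participant x within level, listwise-deleting
# participants with any missing cell, ready for mixed_anova().
.complete_long <- function(d, value_col, within_col) {
  d <- data.table::as.data.table(d)
  out <- data.table::data.table(participant_id = d$participant_id,
                                group = d$group,
                                level = d[[within_col]],
                                value = d[[value_col]])
  bad <- out[is.na(value), unique(participant_id)]
  n_lev <- data.table::uniqueN(out$level)
  cnt <- out[, .N, by = participant_id]
  bad <- union(bad, cnt[N != n_lev, participant_id])
  out[!participant_id %in% bad]
}

#' Run the full statistical battery on derived data
#'
#' Produces the analyses reported for a given design: group x block mixed
#' ANOVAs on normalized training and post-test performance (speed and
#' accuracy), the one-way group ANOVA on learning magnitude with Tukey
#' pairwise follow-ups, group x block / group x rest-interval mixed ANOVAs
#' on the micro-online and micro-offline gains and, for the three-session
#' design, the group x offline-period mixed ANOVA on sequential and random
#' macro-offline gains with per-period one-way follow-ups, per-group
#' one-sample tests of the gains against zero, and the moderated regressions
#' of macro- on micro-offline gains.
#'
#' @param blocks Normalized block table.
#' @param measures Per-participant measures from [derive_measures()] (with
#'   its `micro` attribute).
#' @param experiment 1 or 2.
#' @param gg_alpha Sphericity-trigger level for GG correction.
#' @param compute_bf Compute Bayes factors (slower; lme4 fits).
#' @return Nested list of `anova_result` / `pairwise_result` /
#'   `moderated_regression` objects.
#' @export
run_stats <- function(blocks, measures, experiment, gg_alpha = 0.05,
                      compute_bf = TRUE) {
  b <- data.table::as.data.table(blocks)
  micro <- attr(measures, "micro")
  out <- list()

  tr <- .complete_long(b[session == 1L & run == "training"], "norm_rt", "block")
  out$training_rt <- mixed_anova(tr, gg_alpha = gg_alpha, compute_bf = compute_bf)
  tra <- .complete_long(b[session == 1L & run == "training"], "norm_acc", "block")
  out$training_acc <- mixed_anova(tra, gg_alpha = gg_alpha, compute_bf = compute_bf)
  pt_ <- .complete_long(b[session == 1L & run == "post_test"], "norm_rt", "block")
  out$post_test_rt <- mixed_anova(pt_, gg_alpha = gg_alpha, compute_bf = compute_bf)

  out$lm_anova <- one_way_anova(measures$lm, measures$group, compute_bf = compute_bf)
  out$lm_pairwise <- tukey_pairwise(measures$lm, measures$group,
                                    compute_bf = compute_bf)

  if (!is.null(micro)) {
    mo <- .complete_long(
      merge(micro[measure == "micro_online"],
            unique(measures[, c("participant_id", "group")]),
            by = "participant_id"), "gain", "index")
    out$micro_online <- mixed_anova(mo, gg_alpha = gg_alpha,
                                    compute_bf = compute_bf)
    mf <- .complete_long(
      merge(micro[measure == "micro_offline"],
            unique(measures[, c("participant_id", "group")]),
            by = "participant_id"), "gain", "index")
    out$micro_offline <- mixed_anova(mf, gg_alpha = gg_alpha,
                                     compute_bf = compute_bf)
  }

  if (identical(as.integer(experiment), 2L)) {
    mk_long <- function(cols) {
      data.table::melt(
        data.table::as.data.table(measures)[, c("participant_id", "group", cols),
                                            with = FALSE],
        id.vars = c("participant_id", "group"), variable.name = "level",
        value.name = "value")
    }
    seq_long <- .complete_long(
      mk_long(c("macro_seq_5h", "macro_seq_24h")), "value", "level")
    out$macro_seq <- mixed_anova(seq_long, gg_alpha = gg_alpha,
                                 compute_bf = compute_bf)
    ran_long <- .complete_long(
      mk_long(c("macro_rand_5h", "macro_rand_24h")), "value", "level")
    out$macro_rand <- mixed_anova(ran_long, gg_alpha = gg_alpha,
                                  compute_bf = compute_bf)
    out$macro_seq_5h_anova <- one_way_anova(measures$macro_seq_5h,
                                            measures$group, compute_bf = compute_bf)
    out$macro_seq_24h_anova <- one_way_anova(measures$macro_seq_24h,
                                             measures$group, compute_bf = compute_bf)
    out$macro_seq_5h_pairwise <- tukey_pairwise(measures$macro_seq_5h,
                                                measures$group, compute_bf = compute_bf)
    out$macro_seq_24h_pairwise <- tukey_pairwise(measures$macro_seq_24h,
                                                 measures$group, compute_bf = compute_bf)
    out$gains_vs_zero <- lapply(split(measures, measures$group), function(mg) {
      lapply(c(macro_seq_5h = "macro_seq_5h", macro_seq_24h = "macro_seq_24h"),
             function(col) {
               v <- mg[[col]]
               if (sum(!is.na(v)) >= 2 && sd(v, na.rm = TRUE) > 0) {
                 one_sample_t(v)
               } else NULL
             })
    })
    out$micro_macro_5h <- tryCatch(
      moderated_regression(measures$macro_seq_5h, measures$mean_micro_offline,
                           measures$group, compute_bf = compute_bf),
      error = function(e) NULL)
    out$micro_macro_24h <- tryCatch(
      moderated_regression(measures$macro_seq_24h, measures$mean_micro_offline,
                           measures$group, compute_bf = compute_bf),
      error = function(e) NULL)
  }
  out
}

#' Fit age-trajectory curves for the standard measures
#'
#' Fits the five candidate forms and selects by AIC, separately within the
#' 7-35 and 55-75 age windows (never jointly across the unsampled 36-54
#' gap).
#'
#' @param measures Per-participant measures (with `age`).
#' @param cols Measure columns to fit (defaults depend on availability).
#' @param seed Multi-start seed passed to [select_best_fit()].
#' @return Nested list: fits[[measure]][[window]] -> `fit_result`.
#' @export
fit_age_trajectories <- function(measures, cols = NULL, seed = 1L) {
  m <- data.table::as.data.table(measures)
  if (is.null(cols)) {
    cols <- intersect(c("lm", "mean_micro_online", "mean_micro_offline",
                        "macro_seq_5h", "macro_seq_24h"), names(m))
  }
  windows <- list(`7-35` = c(7, 35), `55-75` = c(55, 75))
  out <- list()
  for (col in cols) {
    out[[col]] <- lapply(windows, function(w) {
      sub <- m[age >= w[1] & age <= w[2] & !is.na(get(col))]
      if (nrow(sub) < 8L) return(NULL)
      tryCatch(select_best_fit(sub$age, sub[[col]], seed = seed),
               error = function(e) NULL)
    })
  }
  out
}

.anova_to_list <- function(a) {
  if (is.null(a)) return(NULL)
  a[c("effect", "F", "df1", "df2", "epsilon_gg", "sphericity_p", "p", "eta2",
      "eta2_ci", "partial_eta2", "bf10")]
}

.stats_to_json <- function(stats) {
  conv <- function(x) {
    if (inherits(x, "anova_result")) return(.anova_to_list(x))
    if (inherits(x, "mixed_anova_result")) {
      return(list(between = .anova_to_list(x$between),
                  within = .anova_to_list(x$within),
                  interaction = .anova_to_list(x$interaction),
                  epsilon_gg = x$epsilon_gg, mauchly_p = x$mauchly_p))
    }
    if (inherits(x, "pairwise_result")) return(as.data.frame(x))
    if (inherits(x, "moderated_regression")) {
      return(list(coefficients = x$coefficients,
                  overall_slope = as.list(x$overall_slope),
                  interaction_bf10 = x$interaction_bf10, r2 = x$r2, n = x$n))
    }
    if (is.list(x)) return(lapply(x, conv))
    x
  }
  lapply(stats, conv)
}

.report_anova_line <- function(label, a) {
  if (is.null(a)) return(character())
  sprintf("- %s: F(%.3f, %.3f) = %.3f, p = %.4g %s%s%s%s",
          label, a$df1, a$df2, a$F, a$p, .trend_flag(a$p),
          if (!is.null(a$partial_eta2) && !is.na(a$partial_eta2))
            sprintf(", partial eta2 = %.3f", a$partial_eta2) else "",
          if (!is.null(a$eta2) && !is.na(a$eta2))
            sprintf(", eta2 = %.3f [%.3f, %.3f]", a$eta2, a$eta2_ci[1],
                    a$eta2_ci[2]) else "",
          if (!is.na(a$bf10)) sprintf(", BF10 = %.4g", a$bf10) else "")
}

.report_mixed <- function(label, mx) {
  if (is.null(mx)) return(character())
  c(sprintf("### %s", label),
    .report_anova_line("group", mx$between),
    if (!is.null(mx$within)) .report_anova_line("within", mx$within),
    if (!is.null(mx$interaction)) .report_anova_line("group x within",
                                                     mx$interaction),
    "")
}

.report_pairwise <- function(label, pw) {
  if (is.null(pw)) return(character())
  c(sprintf("### %s (Tukey)", label),
    vapply(seq_len(nrow(pw)), function(i) {
      sprintf("- %s vs %s: diff = %.4f, p = %.4g %s, g = %.3f [%.3f, %.3f]%s",
              pw$group1[i], pw$group2[i], pw$diff[i], pw$tukey_p[i],
              .trend_flag(pw$tukey_p[i]), pw$hedges_g[i], pw$g_lo[i],
              pw$g_hi[i],
              if (!is.na(pw$bf10[i])) sprintf(", BF10 = %.4g", pw$bf10[i]) else "")
    }, character(1)),
    "")
}

#' Run the end-to-end pipeline
#'
#' simulate (or read) -> validate -> trial exclusion -> block summaries ->
#' baseline normalization -> derived measures -> statistical battery ->
#' age-trajectory fits -> report. Deterministic given (config, seed). When
#' `outdir` is set, writes blocks.csv, measures.csv, exclusions.csv,
#' stats.json, fits.json, report.md (and ground_truth.csv for simulated
#' cohorts); on a stage failure, partial outputs are retained and MANIFEST
#' names the failing stage.
#'
#' @param config An `srtt_config` (see [as_config()] / [read_config()]), a
#'   plain list of overrides, or a path to a YAML config file.
#' @return List with trials, blocks, measures, stats, fits, exclusions,
#'   invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "srtt_config")) config
         else if (is.character(config)) read_config(config)
         else as_config(config)
  outdir <- cfg$outdir
  manifest <- character()
  emit <- function(name, writer) {
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      writer(file.path(outdir, name))
      manifest <<- c(manifest, name)
      writeLines(c(manifest, "status: incomplete"),
                 file.path(outdir, "MANIFEST"))
    }
  }
  stage <- "input"
  result <- tryCatch({
    gt <- NULL
    if (!is.null(cfg$input)) {
      trials <- read_trial_table(cfg$input)
    } else {
      stage <- "simulate"
      cc <- cohort_config(cfg$experiment, cfg$n_per_group,
                          group_params = cfg$group_params, seed = cfg$seed,
                          continuous_age = cfg$continuous_age)
      sim <- simulate_cohort(cc)
      trials <- sim$trials
      gt <- sim$ground_truth
      emit("ground_truth.csv", function(p) data.table::fwrite(gt, p))
    }
    stage <- "validate"
    rep <- validate_trial_table(trials)
    if (!rep$is_valid) {
      stop("trial table failed validation (", nrow(rep$errors), " error(s); ",
           "first: ", rep$errors$rule[1], " at ", rep$errors$location[1], ")")
    }
    stage <- "qc"
    trials <- flag_rt_outliers(trials, k = cfg$k_sd)
    excl <- exclusion_rates(trials)
    emit("exclusions.csv", function(p) {
      data.table::fwrite(trials[excluded == TRUE,
                                .(participant_id, session, run, block, trial, rt_ms)], p)
    })
    stage <- "summarize"
    blocks <- summarize_blocks(trials)
    stage <- "normalize"
    blocks <- baseline_normalize(blocks, raw_mode = cfg$raw_mode)
    emit("blocks.csv", function(p) data.table::fwrite(blocks, p))
    stage <- "derive"
    measures <- derive_measures(trials, blocks, raw_mode = cfg$raw_mode)
    emit("measures.csv", function(p) data.table::fwrite(measures, p))
    stage <- "stats"
    stats <- run_stats(blocks, measures, cfg$experiment,
                       gg_alpha = cfg$gg_alpha, compute_bf = cfg$compute_bf)
    emit("stats.json", function(p) {
      jsonlite::write_json(.stats_to_json(stats), p, auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
    })
    stage <- "curves"
    fits <- fit_age_trajectories(measures, seed = cfg$seed)
    emit("fits.json", function(p) {
      tolist <- function(f) if (is.null(f)) NULL else
        f[intersect(c("form", "params", "rss", "r2", "aic", "F", "df1", "df2",
                      "p", "vertex"), names(f))]
      jsonlite::write_json(lapply(fits, function(w) lapply(w, tolist)), p,
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
    })
    stage <- "report"
    emit("report.md", function(p) {
      lines <- c(
        sprintf("# SRTT pipeline report (experiment %d, seed %d)",
                cfg$experiment, cfg$seed),
        "",
        sprintf("Participants: %d; cohort mean trial exclusion: %.2f%%",
                data.table::uniqueN(blocks$participant_id),
                excl$cohort_mean_pct),
        "",
        .report_mixed("Training: group x block, normalized RT", stats$training_rt),
        .report_mixed("Training: group x block, normalized accuracy",
                      stats$training_acc),
        .report_mixed("Post-test: group x block, normalized RT",
                      stats$post_test_rt),
        "### Learning magnitude (one-way group ANOVA)",
        .report_anova_line("group", stats$lm_anova),
        "",
        .report_pairwise("Learning magnitude", stats$lm_pairwise),
        .report_mixed("Micro-online gains: group x block", stats$micro_online),
        .report_mixed("Micro-offline gains: group x rest interval",
                      stats$micro_offline))
      if (cfg$experiment == 2L) {
        lines <- c(lines,
          .report_mixed("Sequential macro-offline gains: group x offline period",
                        stats$macro_seq),
          .report_mixed("Random macro-offline gains: group x offline period",
                        stats$macro_rand),
          "### Sequential macro gains, per-period group ANOVAs",
          .report_anova_line("5 h", stats$macro_seq_5h_anova),
          .report_anova_line("24 h", stats$macro_seq_24h_anova),
          "",
          .report_pairwise("5 h sequential gains", stats$macro_seq_5h_pairwise),
          .report_pairwise("24 h sequential gains", stats$macro_seq_24h_pairwise))
        if (!is.null(stats$micro_macro_24h)) {
          lines <- c(lines, "### Micro-offline to 24 h macro-offline regression",
                     sprintf("- common slope b = %.3f, p = %.4g %s, interaction-block BF10 = %.4g",
                             stats$micro_macro_24h$overall_slope[["b"]],
                             stats$micro_macro_24h$overall_slope[["p"]],
                             .trend_flag(stats$micro_macro_24h$overall_slope[["p"]]),
                             stats$micro_macro_24h$interaction_bf10), "")
        }
      }
      for (colname in names(fits)) {
        for (w in names(fits[[colname]])) {
          f <- fits[[colname]][[w]]
          if (is.null(f)) next
          lines <- c(lines, sprintf(
            "- best fit, %s vs age (%s): %s, R2 = %.3f, AIC = %.2f%s",
            colname, w, f$form, f$r2, f$aic,
            if (!is.null(f$vertex)) sprintf(", vertex at %.1f years", f$vertex) else ""))
        }
      }
      writeLines(lines, p)
    })
    if (!is.null(outdir)) {
      writeLines(c(manifest, "status: complete"), file.path(outdir, "MANIFEST"))
    }
    list(trials = trials, blocks = blocks, measures = measures, stats = stats,
         fits = fits, exclusions = excl, ground_truth = gt)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
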
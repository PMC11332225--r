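#' @importFrom stats aov anova coef integrate lm model.matrix na.omit pchisq pf
#'   pt ptukey qf qt resid rbinom rnorm runif sd setNames uniroot var BIC
#'   as.formula complete.cases optim quantile
#' @importFrom utils head modifyList read.csv write.csv
NULL

# The deterministic 8-element sequence used in all sequential runs
# (keys numbered 1-8, left pinky to right pinky).
.SRTT_SEQUENCE <- c(4L, 7L, 3L, 8L, 6L, 2L, 5L, 1L)

.TRIALS_PER_BLOCK <- 48L
.REPS_PER_BLOCK <- 6L

.RUN_LEVELS <- c("familiarization", "pre_random", "training", "post_test",
                 "post_random", "retest_seq", "retest_random")
.SEQ_RUNS <- c("training", "post_test", "retest_seq")
.GROUP_LEVELS <- c("CH", "AD", "YA", "OA")

#' The fixed SRTT key sequence
#'
#' Returns the deterministic 8-element sequence cycled in all sequential runs.
#' Keys are numbered 1 (left pinky) to 8 (right pinky).
#'
#' @return Integer vector of length 8.
#' @export
srtt_sequence <- function() .SRTT_SEQUENCE

#' Session/run layout of the two experiments
#'
#' Experiment 1 is a single session: 1 familiarization block (pseudorandom,
#' not analyzed), 4 pre-learning random blocks, 16 training blocks
#' (sequential), 4 post-learning test blocks (sequential) and 4 post-learning
#' random blocks. Experiment 2 adds two retest sessions (approximately 5 h
#' and 24 h after session 1), each with 4 sequential and 4 pseudorandom
#' blocks.
#'
#' @param experiment 1 or 2.
#' @return A data.frame with columns `session`, `run`, `n_blocks`, `variant`
#'   (sequential/pseudorandom), in chronological order.
#' @export
experiment_design <- function(experiment) {
  experiment <- as.integer(experiment)
  if (!experiment %in% c(1L, 2L)) stop("`experiment` must be 1 or 2")
  s1 <- data.frame(
    session = 1L,
    run = c("familiarization", "pre_random", "training", "post_test", "post_random"),
    n_blocks = c(1L, 4L, 16L, 4L, 4L),
    variant = c("pseudorandom", "pseudorandom", "sequential", "sequential", "pseudorandom"),
    stringsAsFactors = FALSE
  )
  if (experiment == 1L) return(s1)
  retest <- function(s) data.frame(
    session = s,
    run = c("retest_seq", "retest_random"),
    n_blocks = c(4L, 4L),
    variant = c("sequential", "pseudorandom"),
    stringsAsFactors = FALSE
  )
  rbind(s1, retest(2L), retest(3L))
}

#' Expected number of blocks for a run
#' @keywords internal
.run_n_blocks <- function(run) {
  c(familiarization = 1L, pre_random = 4L, training = 16L, post_test = 4L,
    post_random = 4L, retest_seq = 4L, retest_random = 4L)[run]
}

#' Generate a target order for a run
#'
#' Sequential runs cycle the fixed 8-element sequence; each 48-press block is
#' six traversals starting at the first element. Pseudorandom runs emit one
#' occurrence of each of the 8 targets per 8-trial window, with the additional
#' constraint that the same target never appears on two consecutive trials --
#' including across window (and hence block) boundaries within the run.
#'
#' Pseudorandom orders are drawn from R's current RNG stream; seed the stream
#' with [set.seed()] for reproducibility.
#'
#' @param variant "sequential" or "pseudorandom".
#' @param n_trials Number of trials; must be a positive multiple of 8.
#' @param prev_last Optional last target of the preceding window, used to
#'   enforce the no-consecutive-repeat constraint across run boundaries.
#' @return Integer vector of targets in 1..8.
#' @export
sequence_order <- function(variant = c("sequential", "pseudorandom"),
                           n_trials, prev_last = NA_integer_) {
  variant <- match.arg(variant)
  n_trials <- as.integer(n_trials)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials <= 0L ||
      n_trials %% 8L != 0L) {
    stop("`n_trials` must be a positive multiple of 8")
  }
  n_win <- n_trials %/% 8L
  if (variant == "sequential") {
    return(rep(.SRTT_SEQUENCE, n_win))
  }
  out <- integer(n_trials)
  last <- as.integer(prev_last)
  for (w in seq_len(n_win)) {
    repeat {
      perm <- sample.int(8L)
      if (is.na(last) || perm[1L] != last) break
    }
    out[(w - 1L) * 8L + 1:8] <- perm
    last <- perm[8L]
  }
  out
}
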
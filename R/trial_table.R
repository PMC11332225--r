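#' @import data.table
NULL

.TRIAL_COLUMNS <- c(
  participant_id = "character", group = "character", age = "numeric",
  experiment = "integer", session = "integer", run = "character",
  block = "integer", trial = "integer", target = "integer",
  response = "integer", correct = "logical", rt_ms = "numeric",
  repetition = "integer"
)

#' Read a keypress-level trial table
#'
#' Reads a CSV with one row per keypress and the fixed lower-snake-case
#' schema: participant_id, group (CH/AD/YA/OA), age, experiment, session,
#' run, block, trial (1-48), target (1-8), response (1-8 or empty), correct,
#' rt_ms, repetition (1-6). Columns are typed on read; rows whose rt_ms does
#' not parse as a number are reported via a "parse_errors" attribute rather
#' than silently dropped.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.table with typed columns; attribute `parse_errors` holds a
#'   data.frame of (row, message) for unparseable rows (possibly empty).
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, colClasses = list(character = "participant_id"),
                           na.strings = c("", "NA"), data.table = TRUE,
                           showProgress = FALSE)
  missing_cols <- setdiff(names(.TRIAL_COLUMNS), names(raw))
  if (length(missing_cols)) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parse_errors <- data.frame(row = integer(), message = character())
  coerce_num <- function(col, as_int = FALSE) {
    v <- raw[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        parse_errors <<- rbind(parse_errors, data.frame(
          row = bad, message = sprintf("non-numeric %s: '%s'", col, v[bad])))
      }
      v <- num
    }
    if (as_int) as.integer(v) else as.numeric(v)
  }
  out <- data.table::data.table(
    participant_id = as.character(raw$participant_id),
    group = as.character(raw$group),
    age = coerce_num("age"),
    experiment = coerce_num("experiment", TRUE),
    session = coerce_num("session", TRUE),
    run = as.character(raw$run),
    block = coerce_num("block", TRUE),
    trial = coerce_num("trial", TRUE),
    target = coerce_num("target", TRUE),
    response = coerce_num("response", TRUE),
    correct = as.logical(raw$correct),
    rt_ms = coerce_num("rt_ms")
  )
  out[, repetition := coerce_num("repetition", TRUE)]
  data.table::setattr(out, "parse_errors", parse_errors)
  out[]
}

#' Write a trial table to CSV
#'
#' Writes exactly the schema columns, UTF-8, comma-delimited, so that
#' [read_trial_table()] round-trips the table field for field.
#'
#' @param x A trial table (data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(x, path) {
  x <- data.table::as.data.table(x)
  data.table::fwrite(x[, names(.TRIAL_COLUMNS), with = FALSE], path)
  invisible(path)
}

.vr <- function(rule, location, message) {
  data.frame(rule = rule, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a trial table against the task-structure invariants
#'
#' Checks every schema invariant: factor levels and ranges, the age windows
#' sampled by the study design (7-35 and 55-75; ages 36-54 are rejected),
#' exactly 48 trials per block with repetition = ceil(trial/8), the expected
#' number of blocks per run, the fixed 4-7-3-8-6-2-5-1 cycle in sequential
#' blocks, the one-per-window/no-consecutive-repeat structure of pseudorandom
#' runs, and correct == (response == target). The validator never throws on a
#' syntactically valid table; all violations are report content.
#'
#' @param x A trial table as returned by [read_trial_table()].
#' @return A list of class `validation_report` with elements `errors`,
#'   `warnings` (data.frames of rule/location/message) and `is_valid`.
#' @export
validate_trial_table <- function(x) {
  x <- data.table::as.data.table(x)
  errors <- list()
  add <- function(e) errors[[length(errors) + 1L]] <<- e
  loc <- function(d) paste0(d$participant_id, "/s", d$session, "/", d$run, "/b", d$block)

  bad <- x[!group %in% .GROUP_LEVELS, unique(group)]
  if (length(bad)) add(.vr("group-level", "table",
                           paste("unknown group:", paste(bad, collapse = ", "))))
  bad_age <- x[!is.na(age) & ((age < 7 | age > 75) | (age > 35 & age < 55)),
               unique(participant_id)]
  for (p in bad_age) add(.vr("age-range", p,
                             "age outside the sampled windows [7,35] U [55,75]"))
  if (any(!x$run %in% .RUN_LEVELS)) {
    add(.vr("run-level", "table", paste("unknown run:",
                                        paste(setdiff(unique(x$run), .RUN_LEVELS), collapse = ", "))))
  }
  if (any(!is.na(x$target) & !(x$target %in% 1:8))) {
    add(.vr("target-range", "table", "target outside 1..8"))
  }
  if (any(!is.na(x$rt_ms) & x$rt_ms <= 0)) {
    add(.vr("rt-positive", "table", "non-positive rt_ms"))
  }
  bad_corr <- x[!is.na(response) & !is.na(correct) & (correct != (response == target))]
  if (nrow(bad_corr)) {
    for (l in unique(loc(bad_corr))) {
      add(.vr("correct-consistency", l, "correct flag inconsistent with response == target"))
    }
  }

  blk <- x[, .(n = .N, rep_ok = all(repetition == ceiling(trial / 8)),
               trials_ok = identical(sort(trial), 1:48)),
           by = .(participant_id, session, run, block)]
  for (i in which(blk$n != .TRIALS_PER_BLOCK)) {
    add(.vr("block-size", loc(blk[i]),
            sprintf("block has %d trials, expected 48", blk$n[i])))
  }
  for (i in which(blk$n == .TRIALS_PER_BLOCK & !blk$trials_ok)) {
    add(.vr("trial-index", loc(blk[i]), "trial indices are not 1..48"))
  }
  for (i in which(blk$n == .TRIALS_PER_BLOCK & blk$trials_ok & !blk$rep_ok)) {
    add(.vr("repetition-index", loc(blk[i]), "repetition != ceil(trial/8)"))
  }

  runs <- x[, .(n_blocks = data.table::uniqueN(block)),
            by = .(participant_id, session, run)]
  runs[, expected := .run_n_blocks(run)]
  for (i in which(!is.na(runs$expected) & runs$n_blocks != runs$expected)) {
    add(.vr("run-blocks",
            paste0(runs$participant_id[i], "/s", runs$session[i], "/", runs$run[i]),
            sprintf("run has %d blocks, expected %d", runs$n_blocks[i], runs$expected[i])))
  }

  seq_blocks <- x[run %in% .SEQ_RUNS]
  if (nrow(seq_blocks)) {
    data.table::setorder(seq_blocks, participant_id, session, run, block, trial)
    chk <- seq_blocks[, .(ok = identical(target, rep(.SRTT_SEQUENCE, .N / 8L))),
                      by = .(participant_id, session, run, block)]
    for (i in which(!chk$ok)) {
      add(.vr("sequence-order", loc(chk[i]),
              "sequential block does not cycle 4-7-3-8-6-2-5-1"))
    }
  }

  ran <- x[!run %in% .SEQ_RUNS]
  if (nrow(ran)) {
    data.table::setorder(ran, participant_id, session, run, block, trial)
    win <- ran[, .(ok = length(unique(target)) == 8L),
               by = .(participant_id, session, run, block, repetition)]
    bad_win <- win[!(ok)]
    for (i in seq_len(nrow(bad_win))) {
      add(.vr("window-permutation",
              paste0(loc(bad_win[i]), "/w", bad_win$repetition[i]),
              "pseudorandom 8-trial window does not contain each target once"))
    }
    rep_chk <- ran[, .(ok = !any(diff(target) == 0L)),
                   by = .(participant_id, session, run)]
    for (i in which(!rep_chk$ok)) {
      add(.vr("consecutive-repeat",
              paste0(rep_chk$participant_id[i], "/s", rep_chk$session[i], "/",
                     rep_chk$run[i]),
              "target repeats on consecutive trials in a pseudorandom run"))
    }
  }

  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(rule = character(), location = character(), message = character())
  structure(list(errors = errors,
                 warnings = data.frame(rule = character(), location = character(),
                                       message = character()),
                 is_valid = nrow(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Trial-table validation:", if (x$is_valid) "VALID" else "INVALID", "\n")
  if (nrow(x$errors)) {
    cat(nrow(x$errors), "error(s):\n")
    print(head(x$errors, 20))
  }
  invisible(x)
}
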
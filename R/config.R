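#' Default pipeline configuration
#'
#' @return Named list of documented defaults: `experiment` (2), `input`
#'   (NULL; when NULL the cohort is simulated), `n_per_group` (27), `k_sd`
#'   (3; trial-exclusion threshold in within-block SDs), `raw_mode` (FALSE;
#'   when TRUE normalized fields pass raw values through, for the
#'   non-normalized sensitivity analyses), `gg_alpha` (0.05; sphericity-test
#'   level that triggers Greenhouse-Geisser correction), `compute_bf` (TRUE),
#'   `continuous_age` (FALSE; when TRUE sequence-specific learning follows a
#'   quadratic function of age), `seed` (1), `outdir` (NULL), `log_level`
#'   ("info").
#' @export
default_config <- function() {
  list(
    experiment = 2L,
    input = NULL,
    n_per_group = 27L,
    k_sd = 3,
    raw_mode = FALSE,
    gg_alpha = 0.05,
    compute_bf = TRUE,
    continuous_age = FALSE,
    seed = 1L,
    outdir = NULL,
    log_level = "info",
    group_params = NULL
  )
}

#' Read a pipeline configuration file
#'
#' Parses a YAML configuration, fills documented defaults, rejects unknown
#' keys and validates parameter ranges.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return A named list (class `srtt_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  as_config(user)
}

#' Coerce a list of overrides into a validated configuration
#'
#' @param user Named list of overrides on [default_config()].
#' @return A validated configuration list of class `srtt_config`.
#' @export
as_config <- function(user = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  if (!cfg$experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2")
  if (!is.numeric(cfg$k_sd) || length(cfg$k_sd) != 1 || cfg$k_sd <= 0) {
    stop("`k_sd` must be a single positive number")
  }
  if (!is.numeric(cfg$n_per_group) || cfg$n_per_group < 1) {
    stop("`n_per_group` must be >= 1")
  }
  if (!is.numeric(cfg$gg_alpha) || cfg$gg_alpha <= 0 || cfg$gg_alpha >= 1) {
    stop("`gg_alpha` must be in (0, 1)")
  }
  if (!is.logical(cfg$raw_mode)) stop("`raw_mode` must be logical")
  cfg$experiment <- as.integer(cfg$experiment)
  cfg$n_per_group <- as.integer(cfg$n_per_group)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "srtt_config"
  cfg
}
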
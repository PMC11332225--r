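#' Moderated regression of macro- on micro-offline gains
#'
#' Ordinary least squares of the macro-offline gain on the mean
#' micro-offline gain, with age-group dummies and group-by-micro interaction
#' terms. The reference group's slope is the `micro` coefficient; each
#' interaction coefficient is the difference between that group's slope and
#' the reference slope. The interaction-block Bayes factor compares the full
#' model with the model without the interaction terms (BIC approximation).
#'
#' @param macro Per-participant macro-offline gain (dependent variable).
#' @param micro Per-participant mean micro-offline gain.
#' @param groups Age-group factor.
#' @param reference Reference group level (default "YA").
#' @param compute_bf Compute the interaction-block BF10.
#' @return List of class `moderated_regression`: `coefficients` (data.frame
#'   term/b/se/t/p), `overall_slope` (b, t, p of micro in the no-interaction
#'   model), `interaction_bf10`, `r2`, `n`.
#' @export
moderated_regression <- function(macro, micro, groups, reference = "YA",
                                 compute_bf = TRUE) {
  keep <- complete.cases(macro, micro, groups)
  d <- data.frame(macro = macro[keep], micro = micro[keep],
                  group = droplevels(factor(groups[keep])))
  if (!reference %in% levels(d$group)) {
    stop("reference group not present: ", reference)
  }
  d$group <- stats::relevel(d$group, ref = reference)
  if (var(d$micro) == 0) stop("constant predictor: design is rank deficient")
  full <- lm(macro ~ micro * group, data = d)
  if (any(is.na(coef(full)))) stop("rank-deficient design")
  reduced <- lm(macro ~ micro + group, data = d)
  # suppressWarnings: exact (zero-residual) fits are legitimate inputs here
  smry <- suppressWarnings(summary(full))
  cf <- smry$coefficients
  coefs <- data.frame(term = rownames(cf), b = cf[, 1], se = cf[, 2],
                      t = cf[, 3], p = cf[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  sl <- suppressWarnings(summary(reduced))$coefficients["micro", ]
  bf <- if (compute_bf) {
    bf_model_comparison(macro ~ micro * group, macro ~ micro + group, d)
  } else NA_real_
  structure(list(coefficients = coefs,
                 overall_slope = c(b = sl[[1]], t = sl[[3]], p = sl[[4]]),
                 interaction_bf10 = bf,
                 r2 = smry$r.squared, n = nrow(d)),
            class = "moderated_regression")
}

#' @export
print.moderated_regression <- function(x, ...) {
  cat(sprintf("Moderated regression (n = %d, R2 = %.3f)\n", x$n, x$r2))
  cat(sprintf("Common slope (no-interaction model): b = %.3f, p = %.4g\n",
              x$overall_slope[["b"]], x$overall_slope[["p"]]))
  print(x$coefficients, digits = 3)
  if (!is.na(x$interaction_bf10)) {
    cat(sprintf("Interaction-block BF10 = %.4g\n", x$interaction_bf10))
  }
  invisible(x)
}
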
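.CURVE_FORMS <- c("linear", "quadratic", "power", "exp1", "exp2")
.CURVE_NPAR <- c(linear = 2L, quadratic = 3L, power = 2L, exp1 = 2L, exp2 = 4L)

.curve_predict <- function(form, params, x) {
  switch(form,
         linear = params[1] + params[2] * x,
         quadratic = params[1] + params[2] * x + params[3] * x^2,
         power = params[1] * x^params[2],
         exp1 = params[1] * exp(params[2] * x),
         exp2 = params[1] * exp(params[2] * x) + params[3] * exp(params[4] * x))
}

# Conditionally-linear residual sum of squares: the amplitude parameters are
# profiled out exactly, leaving a search over the shape parameters only.
.profile_rss <- function(form, shape, x, y) {
  G <- switch(form,
              power = cbind(x^shape[1]),
              exp1 = cbind(exp(shape[1] * x)),
              exp2 = cbind(exp(shape[1] * x), exp(shape[2] * x)))
  if (!all(is.finite(G))) return(list(rss = Inf, amp = rep(NA_real_, ncol(G))))
  fit <- tryCatch(stats::lm.fit(G, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(list(rss = Inf, amp = rep(NA_real_, ncol(G))))
  }
  list(rss = sum(fit$residuals^2), amp = fit$coefficients)
}

#' Fit one candidate age-trajectory form by least squares
#'
#' Forms: linear a + b x; quadratic a + b x + c x^2; power a x^b;
#' single exponential a exp(b x); double exponential
#' a exp(b x) + c exp(d x). Linear and quadratic are exact (lm). Nonlinear
#' forms use a deterministic grid plus seeded random multi-starts over the
#' shape (rate/exponent) parameters with the amplitude parameters profiled
#' out exactly, followed by a Levenberg-Marquardt polish (minpack.lm).
#' AIC = n log(rss/n) + 2 (p + 1), counting the error variance, so rankings
#' are comparable across forms.
#'
#' @param x Predictor (ages; must be > 0 for power/exponential forms).
#' @param y Response.
#' @param form One of "linear", "quadratic", "power", "exp1", "exp2".
#' @param n_starts Random multi-starts added to the deterministic grid.
#' @param seed Seed for the random starts (restores the caller's RNG state).
#' @return List of class `fit_result`: form, params, rss, r2, aic, F, df1,
#'   df2, p, converged, n; quadratic fits also carry `vertex` = -b/(2c).
#' @export
fit_curve <- function(x, y, form = c("linear", "quadratic", "power", "exp1", "exp2"),
                      n_starts = 20L, seed = 1L) {
  form <- match.arg(form)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  npar <- .CURVE_NPAR[[form]]
  n <- length(x)
  if (n < npar + 2L) stop("need at least params + 2 observations")
  if (form %in% c("power", "exp1", "exp2") && any(x <= 0)) {
    stop("power/exponential forms require x > 0")
  }
  sst <- sum((y - mean(y))^2)

  fail <- function() structure(list(form = form, params = NULL, rss = NA_real_,
                                    r2 = NA_real_, aic = NA_real_,
                                    converged = FALSE, n = n),
                               class = "fit_result")
  params <- NULL
  rss <- NA_real_

  if (form %in% c("linear", "quadratic")) {
    X <- if (form == "linear") cbind(1, x) else cbind(1, x, x^2)
    fit <- stats::lm.fit(X, y)
    if (anyNA(fit$coefficients)) return(fail())
    params <- unname(fit$coefficients)
    rss <- sum(fit$residuals^2)
  } else {
    n_shape <- if (form == "exp2") 2L else 1L
    # restore the caller's RNG state after drawing starts
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    span <- max(x) - min(x)
    grid1 <- c(seq(-2, 2, by = 0.25) / max(span / 10, 1), 0.001, -0.001)
    starts <- if (n_shape == 1L) {
      matrix(c(grid1, runif(n_starts, -3, 3) / max(span / 10, 1)), ncol = 1L)
    } else {
      g <- as.matrix(expand.grid(grid1[seq(1, length(grid1), by = 2)],
                                 grid1[seq(1, length(grid1), by = 2)]))
      rbind(g, matrix(runif(2L * n_starts, -3, 3) / max(span / 10, 1),
                      ncol = 2L))
    }
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())

    best <- list(rss = Inf, shape = NULL, amp = NULL)
    for (i in seq_len(nrow(starts))) {
      sh <- starts[i, ]
      pr <- .profile_rss(form, sh, x, y)
      opt <- tryCatch(
        optim(sh, function(s) .profile_rss(form, s, x, y)$rss,
              method = if (n_shape == 1L) "Brent" else "Nelder-Mead",
              lower = if (n_shape == 1L) sh - 2 else -Inf,
              upper = if (n_shape == 1L) sh + 2 else Inf),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value < best$rss) {
        best <- list(rss = opt$value, shape = opt$par,
                     amp = .profile_rss(form, opt$par, x, y)$amp)
      } else if (is.finite(pr$rss) && pr$rss < best$rss) {
        best <- list(rss = pr$rss, shape = sh, amp = pr$amp)
      }
    }
    if (!is.finite(best$rss)) return(fail())
    params <- switch(form,
                     power = c(best$amp[1], best$shape[1]),
                     exp1 = c(best$amp[1], best$shape[1]),
                     exp2 = c(best$amp[1], best$shape[1], best$amp[2], best$shape[2]))
    rss <- best$rss
    # Levenberg-Marquardt polish from the profiled optimum
    fml <- switch(form,
                  power = y ~ a * x^b,
                  exp1 = y ~ a * exp(b * x),
                  exp2 = y ~ a * exp(b * x) + c * exp(d * x))
    start <- switch(form,
                    power = list(a = params[1], b = params[2]),
                    exp1 = list(a = params[1], b = params[2]),
                    exp2 = list(a = params[1], b = params[2],
                                c = params[3], d = params[4]))
    nl <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(nl)) {
      rss_nl <- sum(resid(nl)^2)
      if (is.finite(rss_nl) && rss_nl < rss) {
        params <- unname(coef(nl))
        rss <- rss_nl
      }
    }
  }

  r2 <- 1 - rss / sst
  # fits within ~1e-12 of the total variation are numerically exact; clamp so
  # that exact fits of different forms tie on AIC and parsimony breaks the tie
  rss_eff <- max(rss, sst * 1e-12, .Machine$double.xmin)
  aic <- n * log(rss_eff / n) + 2 * (npar + 1)
  df1 <- npar - 1L
  df2 <- n - npar
  f_stat <- if (rss > 0) ((sst - rss) / df1) / (rss / df2) else Inf
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  out <- list(form = form, params = params, rss = rss, r2 = r2, aic = aic,
              F = f_stat, df1 = df1, df2 = df2, p = p, converged = TRUE, n = n)
  if (form == "quadratic" && params[3] != 0) out$vertex <- -params[2] / (2 * params[3])
  structure(out, class = "fit_result")
}

#' Select the best-fitting age-trajectory form by AIC
#'
#' Fits all candidate forms and returns the converged fit with minimal AIC;
#' ties (within 1e-8) are broken toward the form with fewer parameters.
#'
#' @inheritParams fit_curve
#' @param forms Candidate forms (default all five).
#' @return The winning `fit_result`, with a `ranking` element (data.frame of
#'   form, npar, rss, r2, aic ordered by AIC).
#' @export
select_best_fit <- function(x, y, forms = .CURVE_FORMS, n_starts = 20L,
                            seed = 1L) {
  fits <- lapply(forms, function(fm) {
    tryCatch(fit_curve(x, y, fm, n_starts = n_starts, seed = seed),
             error = function(e) NULL)
  })
  names(fits) <- forms
  ok <- !vapply(fits, is.null, logical(1)) &
    vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic), logical(1))
  if (!any(ok)) stop("no candidate form converged")
  fits <- fits[ok]
  rank_tab <- data.frame(
    form = names(fits),
    npar = .CURVE_NPAR[names(fits)],
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL
  )
  ord <- order(rank_tab$aic + 1e-8 * rank_tab$npar)
  rank_tab <- rank_tab[ord, ]
  best <- fits[[rank_tab$form[1L]]]
  best$ranking <- rank_tab
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): rss = %.4g, R2 = %.3f, AIC = %.2f\n",
              x$form, x$n, x$rss, x$r2, x$aic))
  cat("params:", paste(signif(x$params, 5), collapse = ", "), "\n")
  if (!is.null(x$vertex)) cat(sprintf("vertex (peak age): %.2f\n", x$vertex))
  if (!is.null(x$ranking)) {
    cat("AIC ranking:\n")
    print(x$ranking, digits = 4)
  }
  invisible(x)
}
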
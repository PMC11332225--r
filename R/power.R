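.ncf_power <- function(lambda, df1, df2, alpha) {
  pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' A priori power for a one-way between-subjects ANOVA
#'
#' Noncentral-F power with noncentrality lambda = f^2 N (Cohen's f,
#' G*Power convention), df = (k - 1, N - k).
#'
#' @param f Cohen's f effect size (>= 0).
#' @param k Number of groups.
#' @param N Total sample size (> k).
#' @param alpha Type-I error rate.
#' @return List of class `power_design`: design, f, k, N, alpha, lambda,
#'   df1, df2, power.
#' @export
power_oneway <- function(f, k, N, alpha = 0.05) {
  if (f < 0) stop("f must be >= 0")
  if (N <= k) stop("N must exceed the number of groups")
  lambda <- f^2 * N
  df1 <- k - 1
  df2 <- N - k
  structure(list(design = "oneway", f = f, k = k, m = 1L, rho = NA_real_,
                 N = N, alpha = alpha, lambda = lambda, df1 = df1, df2 = df2,
                 power = .ncf_power(lambda, df1, df2, alpha)),
            class = "power_design")
}

#' A priori power for repeated-measures ANOVA effects
#'
#' G*Power-convention noncentrality for a k-group design with m repeated
#' measurements and correlation rho among them. Between-subjects effect:
#' lambda = f^2 N m / (1 + (m - 1) rho), df = (k - 1, N - k). Within effect:
#' lambda = f^2 N m / (1 - rho), df = (m - 1, (N - k)(m - 1)).
#' Group-by-time interaction: same lambda as within,
#' df = ((k - 1)(m - 1), (N - k)(m - 1)).
#'
#' @param f Cohen's f.
#' @param k Groups; `m` repeated measurements (>= 2); `rho` in [0, 1).
#' @param m,rho,N,alpha Design parameters.
#' @param effect One of "between", "within", "interaction".
#' @return A `power_design` list (see [power_oneway()]).
#' @export
power_repeated <- function(f, k, m, rho, N, alpha = 0.05,
                           effect = c("interaction", "between", "within")) {
  effect <- match.arg(effect)
  if (f < 0) stop("f must be >= 0")
  if (m < 1) stop("m must be >= 1")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (N <= k) stop("N must exceed the number of groups")
  if (effect == "between") {
    lambda <- f^2 * N * m / (1 + (m - 1) * rho)
    df1 <- k - 1
    df2 <- N - k
  } else {
    lambda <- f^2 * N * m / (1 - rho)
    df1 <- if (effect == "within") m - 1 else (k - 1) * (m - 1)
    df2 <- (N - k) * (m - 1)
  }
  structure(list(design = paste0("rm_", effect), f = f, k = k, m = m,
                 rho = rho, N = N, alpha = alpha, lambda = lambda,
                 df1 = df1, df2 = df2,
                 power = .ncf_power(lambda, df1, df2, alpha)),
            class = "power_design")
}

#' Smallest sample size reaching a target power
#'
#' Scans total N upward in multiples of k (equal groups) and returns the
#' first N whose computed power reaches `target_power`.
#'
#' @param f,k,alpha As in the power routines.
#' @param target_power Desired power in (alpha, 1).
#' @param design "oneway" or "repeated".
#' @param m,rho,effect Repeated-measures parameters (ignored for oneway).
#' @param max_N Search cap (error if exceeded).
#' @return A `power_design` at the selected N.
#' @export
required_sample_size <- function(f, k, alpha = 0.05, target_power = 0.80,
                                 design = c("oneway", "repeated"),
                                 m = 2, rho = 0.25, effect = "interaction",
                                 max_N = 1e5) {
  design <- match.arg(design)
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must be in (alpha, 1)")
  }
  if (f <= 0) stop("power cannot reach the target with f = 0")
  N <- 2L * k
  repeat {
    pd <- if (design == "oneway") power_oneway(f, k, N, alpha)
          else power_repeated(f, k, m, rho, N, alpha, effect)
    if (pd$power >= target_power) return(pd)
    N <- N + k
    if (N > max_N) stop("target power unreachable within max_N")
  }
}

#' @export
print.power_design <- function(x, ...) {
  cat(sprintf("%s: f = %.3g, k = %d, N = %d%s, alpha = %.3g\n", x$design,
              x$f, x$k, x$N,
              if (!is.na(x$rho)) sprintf(", m = %d, rho = %.2f", x$m, x$rho) else "",
              x$alpha))
  cat(sprintf("lambda = %.3f, df = (%g, %g), power = %.4f\n",
              x$lambda, x$df1, x$df2, x$power))
  invisible(x)
}
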
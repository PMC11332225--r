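# Invert the noncentral-t CDF to a CI on the noncentrality parameter.
.ncp_t_ci <- function(t_obs, df, conf = 0.95) {
  probs <- c((1 + conf) / 2, (1 - conf) / 2)
  root <- function(target_p) {
    # suppressWarnings: pnt's "full precision" warning at extreme ncp
    f <- function(ncp) suppressWarnings(pt(t_obs, df, ncp = ncp)) - target_p
    lo <- t_obs - 10 - 5 * abs(t_obs)
    hi <- t_obs + 10 + 5 * abs(t_obs)
    while (f(lo) < 0 && lo > -1e6) lo <- lo * 2 - 10
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2 + 10
    uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  vapply(probs, root, numeric(1))
}

#' Hedges' g for two independent samples
#'
#' Small-sample bias-corrected standardized mean difference:
#' g = J (mean_a - mean_b) / s_pooled with J = 1 - 3/(4 df - 1),
#' df = n_a + n_b - 2. The 95% CI is obtained by inverting the noncentral-t
#' distribution of the associated t statistic and rescaling to the g scale.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param conf Confidence level (default 0.95).
#' @return List: g, d (uncorrected), J, ci (length 2).
#' @export
hedges_g <- function(a, b, conf = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs n >= 2")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  md <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (md == 0) {
      return(list(g = 0, d = 0, J = 1 - 3 / (4 * df - 1), ci = c(0, 0)))
    }
    stop("zero pooled variance with unequal means: effect size infinite")
  }
  d <- md / sqrt(sp2)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  scale_t_to_d <- sqrt(1 / na + 1 / nb)
  t_obs <- d / scale_t_to_d
  ncp_ci <- .ncp_t_ci(t_obs, df, conf)
  list(g = g, d = d, J = J, ci = J * ncp_ci * scale_t_to_d)
}

#' One-sample t test with Hedges' g
#'
#' t = (mean - mu0)/(sd/sqrt(n)), two-sided p, and the bias-corrected
#' standardized effect g = J (mean - mu0)/sd, J = 1 - 3/(4 df - 1).
#'
#' @param values Numeric sample (n >= 2, nonzero SD).
#' @param mu0 Null value (default 0).
#' @return List: t, df, p, g, mean, n.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need n >= 2")
  s <- sd(values)
  if (s == 0) stop("zero standard deviation: t undefined")
  df <- n - 1L
  t_stat <- (mean(values) - mu0) / (s / sqrt(n))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  J <- 1 - 3 / (4 * df - 1)
  list(t = t_stat, df = df, p = p, g = J * (mean(values) - mu0) / s,
       mean = mean(values), n = n)
}
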
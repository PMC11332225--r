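# Invert the noncentral-F CDF to a confidence interval on the noncentrality
# parameter, then map to (partial) eta-squared via eta2 = lambda/(lambda + N).
.ncp_f_ci <- function(f_obs, df1, df2, conf = 0.95) {
  lo_p <- (1 + conf) / 2
  hi_p <- (1 - conf) / 2
  pf_nc <- function(l) suppressWarnings(pf(f_obs, df1, df2, ncp = l))
  ncp_root <- function(target_p) {
    if (pf_nc(0) <= target_p) return(0)
    hi <- 10
    while (pf_nc(hi) > target_p && hi < 1e7) hi <- hi * 2
    uniroot(function(l) pf_nc(l) - target_p, c(0, hi), tol = 1e-8)$root
  }
  c(ncp_root(lo_p), ncp_root(hi_p))
}

.eta2_ci <- function(f_obs, df1, df2, conf = 0.95) {
  n_eff <- df1 + df2 + 1
  l <- .ncp_f_ci(f_obs, df1, df2, conf)
  l / (l + n_eff)
}

#' One-way between-subjects ANOVA with eta-squared and Bayes factor
#'
#' Classical F = MSB/MSW; eta2 = SSB/SST with a 95% CI by noncentral-F
#' inversion; BF10 by the BIC approximation comparing the group model against
#' an intercept-only null.
#'
#' @param values Numeric outcome.
#' @param groups Grouping factor (>= 2 groups, each with >= 2 values).
#' @param compute_bf Compute the BIC-approximate BF10 (default TRUE).
#' @return List of class `anova_result`: effect, F, df1, df2, p, eta2,
#'   eta2_ci, bf10, and the sums of squares.
#' @export
one_way_anova <- function(values, groups, compute_bf = TRUE) {
  keep <- complete.cases(values, groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups")
  ns <- table(groups)
  if (any(ns < 2L)) stop("every group needs >= 2 values")
  n_tot <- length(values)
  gm <- mean(values)
  group_means <- tapply(values, groups, mean)
  ssb <- sum(ns * (group_means - gm)^2)
  sst <- sum((values - gm)^2)
  ssw <- sst - ssb
  if (sst <= 0) stop("zero total variance: F undefined")
  df1 <- k - 1L
  df2 <- n_tot - k
  f_stat <- (ssb / df1) / (ssw / df2)
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  eta2 <- ssb / sst
  bf10 <- NA_real_
  if (compute_bf) {
    d <- data.frame(y = values, g = groups)
    bf10 <- exp((BIC(lm(y ~ 1, d)) - BIC(lm(y ~ g, d))) / 2)
  }
  structure(list(effect = "group", F = f_stat, df1 = df1, df2 = df2,
                 epsilon_gg = NA_real_, sphericity_p = NA_real_, p = p,
                 eta2 = eta2, eta2_ci = .eta2_ci(f_stat, df1, df2),
                 bf10 = bf10, ss = c(between = ssb, within = ssw, total = sst),
                 n = n_tot, k = k),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s: F(%.3f, %.3f) = %.3f, p = %.4g", x$effect, x$df1, x$df2,
              x$F, x$p))
  if (!is.na(x$epsilon_gg)) cat(sprintf(", GG epsilon = %.3f", x$epsilon_gg))
  if (!is.null(x$eta2) && !is.na(x$eta2)) {
    cat(sprintf(", eta2 = %.3f [%.3f, %.3f]", x$eta2, x$eta2_ci[1], x$eta2_ci[2]))
  }
  if (!is.null(x$partial_eta2) && !is.na(x$partial_eta2)) {
    cat(sprintf(", partial eta2 = %.3f", x$partial_eta2))
  }
  if (!is.na(x$bf10)) cat(sprintf(", BF10 = %.4g", x$bf10))
  cat("\n")
  invisible(x)
}

# Orthonormal contrasts over m within-subject levels (rows of C are the
# m-1 normalized Helmert contrasts; C %*% t(C) = I).
.orthonormal_contrasts <- function(m) {
  C <- t(stats::contr.helmert(m))
  C / sqrt(rowSums(C^2))
}

# Greenhouse-Geisser epsilon and Mauchly sphericity test from the pooled
# within-group covariance of the m within-subject levels.
.sphericity <- function(Y, groups) {
  m <- ncol(Y)
  k <- nlevels(groups)
  n <- nrow(Y)
  S <- matrix(0, m, m)
  for (g in levels(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    S <- S + crossprod(scale(Yg, scale = FALSE))
  }
  S <- S / (n - k)
  C <- .orthonormal_contrasts(m)
  M <- C %*% S %*% t(C)
  q <- m - 1L
  eps <- sum(diag(M))^2 / (q * sum(M * M))
  eps <- min(max(eps, 1 / q), 1)
  W <- det(M) / (sum(diag(M)) / q)^q
  f <- n - k
  d <- 1 - (2 * q^2 + q + 2) / (6 * q * f)
  chi2 <- -f * d * log(max(W, .Machine$double.xmin))
  df_chi <- q * (q + 1) / 2 - 1
  p_mauchly <- if (df_chi > 0) pchisq(chi2, df_chi, lower.tail = FALSE) else NA_real_
  list(epsilon = eps, mauchly_W = W, mauchly_p = p_mauchly)
}

#' Mixed (split-plot) ANOVA: between groups x within levels
#'
#' Classical univariate mixed-model partitioning with a subject random
#' effect: the between-subjects factor is tested against subjects-within-
#' groups; the within factor and the interaction against the level-by-
#' subject residual. Within-subject effects are computed through orthonormal
#' contrasts with sum-to-zero group coding, which yields Type-III sums of
#' squares under unbalanced group sizes. Mauchly's test is run on the
#' contrast covariance; when it rejects at `gg_alpha` and the within factor
#' has more than 2 levels, Greenhouse-Geisser epsilon multiplies the within
#' and interaction dfs. Partial eta-squared per effect; BF10 per effect by
#' BIC-approximate comparison of mixed models (lme4, subject random
#' intercept): main effects against the subjects-only null, the interaction
#' against the two-main-effects model.
#'
#' @param data Long-format data.frame.
#' @param value,participant,group,within Column names (strings).
#' @param gg_alpha Mauchly p-value below which GG correction is applied.
#' @param compute_bf Compute BFs (lme4 fits; default TRUE).
#' @return List of class `mixed_anova_result` with `anova_result` elements
#'   `between`, `within`, `interaction`, plus `epsilon_gg`, `mauchly_p`, `m`.
#' @export
mixed_anova <- function(data, value = "value", participant = "participant_id",
                        group = "group", within = "level",
                        gg_alpha = 0.05, compute_bf = TRUE) {
  d <- data.frame(y = data[[value]], id = factor(data[[participant]]),
                  g = factor(data[[group]]), w = factor(data[[within]]))
  if (anyNA(d$y)) {
    stop("missing cells: apply listwise deletion upstream before mixed_anova()")
  }
  tab <- table(d$id, d$w)
  if (any(tab != 1L)) {
    stop("design must be complete: exactly one value per participant x level")
  }
  m <- nlevels(d$w)
  k <- nlevels(d$g)
  if (m == 1L) {
    res <- one_way_anova(d$y, d$g, compute_bf = compute_bf)
    return(structure(list(between = res, within = NULL, interaction = NULL,
                          epsilon_gg = 1, mauchly_p = NA_real_, m = 1L),
                     class = "mixed_anova_result"))
  }
  Y <- as.matrix(data.table::dcast(data.table::as.data.table(d), id ~ w,
                                   value.var = "y")[, -1])
  ids <- data.table::dcast(data.table::as.data.table(d), id ~ w,
                           value.var = "y")$id
  grp <- droplevels(factor(d$g[match(ids, d$id)]))
  n <- nrow(Y)

  # Between-subjects stratum: one-way ANOVA on subject means, scaled by m.
  u <- rowMeans(Y)
  gm <- mean(u)
  ns <- table(grp)
  means_g <- tapply(u, grp, mean)
  ss_group <- m * sum(ns * (means_g - gm)^2)
  ss_subj <- m * (sum((u - gm)^2) - sum(ns * (means_g - gm)^2))
  df_g <- k - 1L
  df_s <- n - k
  f_between <- (ss_group / df_g) / (ss_subj / df_s)
  p_between <- pf(f_between, df_g, df_s, lower.tail = FALSE)

  # Within-subject stratum via orthonormal contrasts; contr.sum coding makes
  # the intercept/group hypotheses Type III under unbalanced groups.
  C <- .orthonormal_contrasts(m)
  Z <- Y %*% t(C)
  X <- model.matrix(~grp, contrasts.arg = list(grp = "contr.sum"))
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Z)
  E <- crossprod(Z - X %*% B)
  ss_err_w <- sum(diag(E))
  hyp_ss <- function(rows) {
    L <- diag(ncol(X))[rows, , drop = FALSE]
    LB <- L %*% B
    sum(diag(t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB))
  }
  ss_within <- hyp_ss(1L)
  ss_inter <- hyp_ss(2:k)
  df_w <- m - 1L
  df_i <- (k - 1L) * (m - 1L)
  df_e <- (n - k) * (m - 1L)
  f_within <- (ss_within / df_w) / (ss_err_w / df_e)
  f_inter <- (ss_inter / df_i) / (ss_err_w / df_e)

  sph <- if (m > 2L) .sphericity(Y, grp) else
    list(epsilon = 1, mauchly_p = NA_real_)
  eps <- 1
  if (m > 2L && is.finite(sph$mauchly_p) && sph$mauchly_p < gg_alpha) {
    eps <- sph$epsilon
  }
  adj <- function(f, df1, df2) {
    list(df1 = eps * df1, df2 = eps * df2,
         p = pf(f, eps * df1, eps * df2, lower.tail = FALSE))
  }
  aw <- adj(f_within, df_w, df_e)
  ai <- adj(f_inter, df_i, df_e)

  bf <- c(between = NA_real_, within = NA_real_, interaction = NA_real_)
  if (compute_bf) bf <- .mixed_bf(d)

  mk <- function(effect, f, df1, df2, p, ss_eff, ss_err, bf10) {
    structure(list(effect = effect, F = f, df1 = df1, df2 = df2,
                   epsilon_gg = if (effect == "group") NA_real_ else eps,
                   sphericity_p = if (effect == "group") NA_real_ else sph$mauchly_p,
                   p = p, eta2 = NA_real_,
                   eta2_ci = .eta2_ci(f, df1, df2),
                   partial_eta2 = ss_eff / (ss_eff + ss_err),
                   bf10 = bf10, n = n, k = k),
              class = "anova_result")
  }
  structure(list(
    between = mk("group", f_between, df_g, df_s, p_between, ss_group, ss_subj,
                 bf[["between"]]),
    within = mk("within", f_within, aw$df1, aw$df2, aw$p, ss_within, ss_err_w,
                bf[["within"]]),
    interaction = mk("group:within", f_inter, ai$df1, ai$df2, ai$p, ss_inter,
                     ss_err_w, bf[["interaction"]]),
    epsilon_gg = eps, mauchly_p = sph$mauchly_p, m = m,
    ss = c(group = ss_group, subj = ss_subj, within = ss_within,
           interaction = ss_inter, error_within = ss_err_w)
  ), class = "mixed_anova_result")
}

# BIC-approximate BF10 per effect, with the subject random intercept in every
# model (lme4, ML fits). Main effects compare against the subjects-only null;
# the interaction compares the full model against both main effects.
.mixed_bf <- function(d) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  fit <- function(fml) suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = d, REML = FALSE, control = ctrl)))
  bic_null <- BIC(fit(y ~ 1 + (1 | id)))
  bic_g <- BIC(fit(y ~ g + (1 | id)))
  bic_w <- BIC(fit(y ~ w + (1 | id)))
  bic_gw <- BIC(fit(y ~ g + w + (1 | id)))
  bic_full <- BIC(fit(y ~ g * w + (1 | id)))
  c(between = exp((bic_null - bic_g) / 2),
    within = exp((bic_null - bic_w) / 2),
    interaction = exp((bic_gw - bic_full) / 2))
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  for (e in c("between", "within", "interaction")) {
    if (!is.null(x[[e]])) print(x[[e]])
  }
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Tukey(-Kramer) p-values from the studentized-range distribution using the
#' one-way ANOVA's within-group mean square, for every unordered pair of
#' groups, with Hedges' g (and its noncentral-t CI) and a JZS t-test BF10
#' per pair.
#'
#' @inheritParams one_way_anova
#' @return data.frame of class `pairwise_result`: group1, group2, diff
#'   (mean1 - mean2), tukey_p, hedges_g, g_lo, g_hi, bf10.
#' @export
tukey_pairwise <- function(values, groups, compute_bf = TRUE) {
  keep <- complete.cases(values, groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  a <- one_way_anova(values, groups, compute_bf = FALSE)
  msw <- a$ss[["within"]] / a$df2
  lv <- levels(groups)
  k <- length(lv)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- values[groups == lv[i]]
      xj <- values[groups == lv[j]]
      diff_ij <- mean(xi) - mean(xj)
      se <- sqrt(msw / 2 * (1 / length(xi) + 1 / length(xj)))
      q_obs <- abs(diff_ij) / se
      p_tukey <- ptukey(q_obs, k, a$df2, lower.tail = FALSE)
      g <- hedges_g(xi, xj)
      bf <- NA_real_
      if (compute_bf) {
        tt <- (mean(xi) - mean(xj)) /
          sqrt(((length(xi) - 1) * var(xi) + (length(xj) - 1) * var(xj)) /
                 (length(xi) + length(xj) - 2) *
                 (1 / length(xi) + 1 / length(xj)))
        bf <- jzs_bf_ttest(tt, length(xi), length(xj))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lv[i], group2 = lv[j], diff = diff_ij, tukey_p = p_tukey,
        hedges_g = g$g, g_lo = g$ci[1], g_hi = g$ci[2], bf10 = bf,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_result", "data.frame")
  out
}
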
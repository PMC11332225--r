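# brute-force one-way ANOVA via explicit sums of squares
brute_oneway <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- nlevels(groups); n <- length(values)
  list(F = (ssb / (k - 1)) / (ssw / (n - k)), eta2 = ssb / (ssb + ssw))
}

test_that("one-way ANOVA matches hand sums of squares", {
  a <- one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                     rep(c("A", "B", "C"), each = 3), compute_bf = FALSE)
  expect_equal(a$F, 3.0)
  expect_equal(a$df1, 2L)
  expect_equal(a$df2, 6L)
  expect_equal(a$eta2, 0.5)
  expect_true(a$eta2 >= a$eta2_ci[1] && a$eta2 <= a$eta2_ci[2])

  same <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3),
                        compute_bf = FALSE)
  expect_equal(same$F, 0)
  expect_equal(same$eta2, 0)

  expect_error(one_way_anova(c(1, 2, 3), c("A", "A", "B")), ">= 2")
  expect_error(one_way_anova(rep(5, 6), rep(c("A", "B"), 3)), "variance")
})

test_that("one-way F equals brute force on random small instances", {
  set.seed(123)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    ns <- sample(2:10, k, replace = TRUE)
    values <- rnorm(sum(ns))
    groups <- rep(LETTERS[1:k], ns)
    a <- one_way_anova(values, groups, compute_bf = FALSE)
    b <- brute_oneway(values, groups)
    expect_equal(a$F, b$F, tolerance = 1e-10)
    expect_equal(a$eta2, b$eta2, tolerance = 1e-10)
  }
})

test_that("mixed ANOVA matches a brute-force cell-means decomposition (2x2)", {
  set.seed(5)
  d <- expand.grid(participant_id = sprintf("P%02d", 1:12),
                   level = c("L1", "L2"), stringsAsFactors = FALSE)
  d$group <- rep(rep(c("G1", "G2"), each = 6), 2)
  d$value <- rnorm(24) + 0.5 * (d$group == "G2") + 0.3 * (d$level == "L2") +
    0.4 * (d$group == "G2") * (d$level == "L2")
  res <- mixed_anova(d, gg_alpha = 0.05, compute_bf = FALSE)

  # brute force from cell/subject means (balanced 2x2)
  Y <- matrix(d$value[order(d$level, d$participant_id)], ncol = 2)
  grp <- rep(c("G1", "G2"), each = 6)
  m <- 2; n <- 12; k <- 2
  u <- rowMeans(Y); gm <- mean(Y)
  ss_group <- m * sum(tapply(u, grp, length) * (tapply(u, grp, mean) - gm)^2)
  ss_subj <- m * sum((u - tapply(u, grp, mean)[grp])^2)
  lev_means <- colMeans(Y)
  ss_level <- n * sum((lev_means - gm)^2)
  cells <- outer(c("G1", "G2"), 1:2,
                 Vectorize(function(g, j) mean(Y[grp == g, j])))
  grp_means <- tapply(u, grp, mean)
  ss_inter <- 6 * sum((cells - outer(grp_means, rep(1, 2)) -
                         outer(rep(1, 2), lev_means) + gm)^2)
  sst <- sum((Y - gm)^2)
  ss_err <- sst - ss_group - ss_subj - ss_level - ss_inter
  expect_equal(res$between$F, (ss_group / 1) / (ss_subj / 10), tolerance = 1e-10)
  expect_equal(res$within$F, (ss_level / 1) / (ss_err / 10), tolerance = 1e-10)
  expect_equal(res$interaction$F, (ss_inter / 1) / (ss_err / 10),
               tolerance = 1e-10)
  # two-level within factor: epsilon = 1, dfs unadjusted
  expect_equal(res$epsilon_gg, 1)
  expect_equal(res$within$df1, 1)
  expect_equal(res$within$df2, 10)
})

test_that("mixed ANOVA agrees with car::Anova on an unbalanced 4-group design", {
  set.seed(17)
  ns <- c(9, 8, 7, 10); m <- 4
  d <- do.call(rbind, lapply(1:4, function(g) {
    do.call(rbind, lapply(seq_len(ns[g]), function(i) {
      data.frame(participant_id = paste0(g, "_", i), group = paste0("G", g),
                 level = paste0("L", 1:m),
                 value = rnorm(1, g / 2) + cumsum(rnorm(m, 0.1 * g, 0.6)))
    }))
  }))
  mine <- mixed_anova(d, gg_alpha = 1, compute_bf = FALSE)  # force GG always

  wide <- data.table::dcast(data.table::as.data.table(d),
                            participant_id + group ~ level,
                            value.var = "value")
  grp <- factor(wide$group)
  Y <- as.matrix(wide[, -(1:2)])
  mlm <- lm(Y ~ grp, contrasts = list(grp = stats::contr.sum))
  a <- car::Anova(mlm, idata = data.frame(level = factor(paste0("L", 1:m))),
                  idesign = ~level, type = 3)
  s <- summary(a, multivariate = FALSE)
  ut <- s$univariate.tests
  expect_equal(mine$between$F, ut["grp", "F value"], tolerance = 1e-8)
  expect_equal(mine$within$F, ut["level", "F value"], tolerance = 1e-8)
  expect_equal(mine$interaction$F, ut["grp:level", "F value"], tolerance = 1e-8)
  expect_equal(mine$epsilon_gg, unname(s$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-8)
  expect_equal(mine$within$p, unname(s$pval.adjustments["level", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("mixed ANOVA with one within level degenerates to the one-way ANOVA", {
  set.seed(29)
  d <- data.frame(participant_id = paste0("P", 1:30),
                  group = rep(c("A", "B", "C"), each = 10),
                  level = "only", value = rnorm(30, rep(c(0, 0.5, 1), each = 10)))
  mx <- mixed_anova(d, compute_bf = FALSE)
  ow <- one_way_anova(d$value, d$group, compute_bf = FALSE)
  expect_equal(mx$between$F, ow$F)
  expect_equal(mx$between$p, ow$p)
})

test_that("mixed ANOVA rejects incomplete designs", {
  d <- data.frame(participant_id = c("P1", "P1", "P2"),
                  group = "A", level = c("L1", "L2", "L1"), value = 1:3)
  expect_error(mixed_anova(d), "complete")
})

test_that("Tukey pairwise matches TukeyHSD and is relabeling-invariant", {
  set.seed(37)
  values <- rnorm(30, rep(c(0, 0.5, 2), each = 10))
  groups <- rep(c("A", "B", "C"), each = 10)
  mine <- tukey_pairwise(values, groups, compute_bf = FALSE)
  ref <- TukeyHSD(aov(values ~ factor(groups)))$`factor(groups)`
  for (i in seq_len(nrow(mine))) {
    key <- paste0(mine$group2[i], "-", mine$group1[i])
    expect_equal(mine$tukey_p[i], ref[key, "p adj"], tolerance = 1e-6)
    expect_equal(-mine$diff[i], ref[key, "diff"], tolerance = 1e-10)
  }
  # relabeling invariance
  relab <- c(A = "Z", B = "Q", C = "M")[groups]
  mine2 <- tukey_pairwise(values, relab, compute_bf = FALSE)
  expect_setequal(round(mine$tukey_p, 10), round(mine2$tukey_p, 10))

  same <- tukey_pairwise(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3),
                         compute_bf = FALSE)
  expect_true(all(same$tukey_p > 0.999))

  far <- tukey_pairwise(c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)),
                        rep(c("A", "B"), each = 5), compute_bf = FALSE)
  expect_lt(far$tukey_p[1], 0.001)
})

test_that("Hedges' g matches direct arithmetic and is antisymmetric", {
  g0 <- hedges_g(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(g0$g, 0)

  g <- hedges_g(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(g$d, -sqrt(3), tolerance = 1e-10)
  expect_equal(g$J, 1 - 3 / 23)
  expect_equal(g$g, (1 - 3 / 23) * -sqrt(3), tolerance = 1e-10)
  expect_true(g$ci[1] <= g$g && g$g <= g$ci[2])

  set.seed(43)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  expect_equal(hedges_g(a, b)$g, -hedges_g(b, a)$g, tolerance = 1e-12)

  expect_error(hedges_g(c(1, 1), c(2, 2)), "infinite")
})

test_that("one-sample t matches direct arithmetic", {
  r <- one_sample_t(c(1, 2, 3), mu0 = 2)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r <- one_sample_t(c(1, 2, 3), mu0 = 0)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_error(one_sample_t(c(2, 2, 2)), "zero")
})

test_that("one-sample t is calibrated on null gains", {
  set.seed(53)
  rejections <- mean(replicate(600, one_sample_t(rnorm(27, 0, 0.05))$p < 0.05))
  expect_lt(abs(rejections - 0.05), 0.025)
})

test_that("JZS Bayes factor behaves and matches an independent quadrature oracle", {
  # data at t = 0 favor the null for any n
  for (n in c(5, 20, 80, 300)) expect_lt(jzs_bf_ttest(0, n, n), 1)
  # strictly increasing in |t| at fixed n
  bfs <- vapply(seq(0, 5, by = 0.5), jzs_bf_ttest, numeric(1), n1 = 25, n2 = 25)
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bf_ttest(Inf, 10, 10), "finite")

  # independent oracle: fixed-grid quadrature on u = g/(1+g)
  oracle <- function(t, n1, n2 = NULL, r = sqrt(2) / 2) {
    if (is.null(n2)) { n_eff <- n1; nu <- n1 - 1 }
    else { n_eff <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2 }
    u <- seq(1e-7, 1 - 1e-7, length.out = 400000)
    g <- u / (1 - u)
    f <- (1 + n_eff * g * r^2)^(-0.5) *
      (1 + t^2 / ((1 + n_eff * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g)) / (1 - u)^2
    num <- sum(f) * (u[2] - u[1])
    num / (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  cases <- list(c(2.5, 30, 30), c(3.2, 33, 32), c(-2, 15, 18))
  for (cs in cases) {
    expect_equal(jzs_bf_ttest(cs[1], cs[2], cs[3]), oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-4)
  }
  # frozen external reference values (pingouin 0.6.1, default Cauchy scale)
  expect_equal(jzs_bf_ttest(2.5, 30, 30), 3.37887, tolerance = 1e-4)
  expect_equal(jzs_bf_ttest(0, 25, 25), 0.28270, tolerance = 1e-3)
  expect_equal(jzs_bf_ttest(1.5, 20), 0.60917, tolerance = 1e-3)
})

test_that("BIC model-comparison BF is 1 for identical models and tracks effects", {
  set.seed(59)
  d <- data.frame(y = rnorm(108), g = factor(rep(c("A", "B", "C", "D"), 27)))
  expect_equal(bf_model_comparison(y ~ g, y ~ g, d), 1)
  expect_error(bf_model_comparison(y ~ 1, y ~ g, d), "nested")

  # strong group effect (Cohen's f approx 1): decisive evidence
  d$y2 <- rnorm(108) + 0.9 * as.integer(d$g)
  expect_gt(bf_model_comparison(y2 ~ g, y2 ~ 1, d), 10)

  # null simulations: median BF below 1
  meds <- replicate(100, {
    d$y3 <- rnorm(108)
    bf_model_comparison(y3 ~ g, y3 ~ 1, d)
  })
  expect_lt(median(meds), 1)
})

test_that("moderated regression recovers constructed slopes exactly", {
  set.seed(61)
  groups <- factor(rep(c("CH", "AD", "YA", "OA"), each = 20))
  x <- rnorm(80)
  y <- 0.5 * x
  r <- moderated_regression(y, x, groups, compute_bf = FALSE)
  cf <- setNames(r$coefficients$b, r$coefficients$term)
  expect_equal(unname(cf["micro"]), 0.5, tolerance = 1e-10)
  inter <- grep(":", names(cf), value = TRUE)
  expect_equal(unname(cf[inter]), rep(0, 3), tolerance = 1e-8)

  # YA slope 0.6, CH slope 0: CH interaction = -0.6
  y2 <- ifelse(groups == "CH", 0, 0.6 * x)
  y2[groups %in% c("AD", "OA")] <- 0.6 * x[groups %in% c("AD", "OA")]
  r2 <- moderated_regression(y2, x, groups, compute_bf = FALSE)
  cf2 <- setNames(r2$coefficients$b, r2$coefficients$term)
  expect_equal(unname(cf2["micro"]), 0.6, tolerance = 1e-10)
  expect_equal(unname(cf2["micro:groupCH"]), -0.6, tolerance = 1e-10)

  expect_error(moderated_regression(y, rep(1, 80), groups), "constant|rank")
})
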
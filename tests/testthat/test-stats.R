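test_that("one-way ANOVA matches the sums-of-squares oracle", {
  # tiny instance: 3 groups x 4 observations, F from explicit SS ratio
  set.seed(51)
  df <- data.frame(y = rnorm(12), g = rep(c("a", "b", "c"), each = 4))
  out <- one_way_anova(df, y, g)
  gm <- mean(df$y)
  means <- tapply(df$y, df$g, mean)
  ss_b <- sum(4 * (means - gm)^2)
  ss_w <- sum((df$y - means[df$g])^2)
  f_oracle <- (ss_b / 2) / (ss_w / 9)
  expect_equal(out$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 9)
  expect_equal(out$partial_eta_sq, ss_b / (ss_b + ss_w), tolerance = 1e-9)
  # identical group means -> F = 0
  df0 <- data.frame(y = rep(c(1, 2, 3, 4), 3),
                    g = rep(c("a", "b", "c"), each = 4))
  expect_equal(one_way_anova(df0, y, g)$statistic, 0)
  # 171 subjects in 3 groups -> df (2, 168)
  df171 <- data.frame(y = rnorm(171),
                      g = rep(c("a", "b", "c"), c(56, 57, 58)))
  out171 <- one_way_anova(df171, y, g)
  expect_equal(c(out171$df1, out171$df2), c(2, 168))
})

test_that("mixed ANOVA matches a hand cell-mean decomposition on a 3x2 toy", {
  set.seed(52)
  n_per <- 3
  df <- expand.grid(subject = 1:(3 * n_per), condition = c("w1", "w2"))
  df$group <- rep(c("g1", "g2", "g3"), each = n_per)[df$subject]
  df$y <- rnorm(nrow(df)) + as.numeric(df$condition == "w2") * 0.5
  out <- mixed_anova(df, y, group, within = "condition")
  # oracle: split-plot SS from cell means
  subj_mean <- as.vector(tapply(df$y, df$subject, mean))
  grand <- mean(df$y)
  grp_of <- df$group[match(sort(unique(df$subject)), df$subject)]
  grp_means <- tapply(subj_mean, grp_of, mean)
  ss_between_subj <- 2 * sum((subj_mean - grand)^2)
  ss_group <- 2 * n_per * sum((grp_means - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  cond_means <- tapply(df$y, df$condition, mean)
  ss_cond <- 3 * n_per * sum((cond_means - grand)^2)
  cell_means <- tapply(df$y, list(df$group, df$condition), mean)
  ss_cells <- n_per * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_group - ss_cond
  ss_total <- sum((df$y - grand)^2)
  ss_within_err <- ss_total - ss_between_subj - ss_cond - ss_int
  f_group <- (ss_group / 2) / (ss_subj_err / (3 * n_per - 3))
  f_cond <- (ss_cond / 1) / (ss_within_err / (3 * n_per - 3))
  f_int <- (ss_int / 2) / (ss_within_err / (3 * n_per - 3))
  expect_equal(out$statistic[out$effect == "group"], f_group,
               tolerance = 1e-9)
  expect_equal(out$statistic[out$effect == "condition"], f_cond,
               tolerance = 1e-9)
  expect_equal(out$statistic[out$effect == "group x condition"], f_int,
               tolerance = 1e-9)
  # condition effect constructed to be exactly zero -> within F = 0
  df2 <- df
  base <- rnorm(3 * n_per)
  delta <- rnorm(3 * n_per)
  delta <- delta - mean(delta)
  df2$y <- c(base, base + delta)
  out2 <- mixed_anova(df2, y, group, within = "condition")
  expect_equal(out2$statistic[out2$effect == "condition"], 0,
               tolerance = 1e-9)
  expect_error(mixed_anova(df[-1, ], y, group, within = "condition"),
               "unbalanced")
})

test_that("between-effect df are (2, 168) at 171 subjects and match one-way on 1-level within", {
  set.seed(53)
  df <- expand.grid(subject = 1:171, condition = c("massage", "touch"))
  df$group <- rep(c("in", "or", "pl"), c(56, 57, 58))[df$subject]
  df$y <- rnorm(nrow(df))
  out <- mixed_anova(df, y, group, within = "condition")
  expect_equal(out$df1[out$effect == "group"], 2)
  expect_equal(out$df2[out$effect == "group"], 168)
  # reduction property: averaging the two conditions reproduces the
  # between-group F of a one-way ANOVA on subject means
  subj <- aggregate(y ~ subject + group, df, mean)
  ow <- one_way_anova(subj, y, group)
  expect_equal(out$statistic[out$effect == "group"], ow$statistic,
               tolerance = 1e-9)
  expect_equal(ow$df2, 168)
})

test_that("Bonferroni adjustment caps and scales", {
  expect_equal(bonferroni_pairwise(0.02, 3), 0.06)
  expect_equal(bonferroni_pairwise(0.5, 3), 1.0)
  p <- c(0.01, 0.2)
  for (m in 1:6) {
    expect_true(all(bonferroni_pairwise(p, m) <= 1))
    if (m > 1)
      expect_true(all(bonferroni_pairwise(p, m) >=
                        bonferroni_pairwise(p, m - 1)))
  }
  expect_error(bonferroni_pairwise(0.5, 0), "m must be")
})

test_that("Spearman's rho matches the rank-then-Pearson oracle", {
  df <- data.frame(x = 1:10, y = exp(1:10))
  expect_equal(spearman_rho(df, x, y)$rho, 1)
  df$y2 <- -df$y
  expect_equal(spearman_rho(df, x, y2)$rho, -1)
  set.seed(54)
  d2 <- data.frame(x = rnorm(20), y = rnorm(20))
  got <- spearman_rho(d2, x, y)
  oracle <- cor(rank(d2$x), rank(d2$y))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_error(spearman_rho(data.frame(x = rep(1, 5), y = 1:5), x, y),
               "constant")
})

test_that("mediation satisfies the OLS identity and the full-mediation case", {
  set.seed(55)
  n <- 60
  x <- rnorm(n)
  m <- 0.8 * x + rnorm(n)
  y <- 0.5 * x + 0.3 * m + rnorm(n)
  fit <- mediate(data.frame(x, m, y), x, m, y, n_boot = 200, seed = 1)
  expect_equal(fit$c, fit$c_prime + fit$indirect, tolerance = 1e-9)
  # oracle: lm coefficient paths
  expect_equal(fit$a, coef(lm(m ~ x))[["x"]], tolerance = 1e-9)
  expect_equal(fit$b, coef(lm(y ~ x + m))[["m"]], tolerance = 1e-9)
  expect_equal(fit$c_prime, coef(lm(y ~ x + m))[["x"]], tolerance = 1e-9)
  expect_equal(fit$c, coef(lm(y ~ x))[["x"]], tolerance = 1e-9)
  # full mediation by construction: Y = M, M depends on X
  x2 <- rep(0:1, each = 30)
  m2 <- x2 + rnorm(60, 0, 0.2)
  fit2 <- mediate(data.frame(x = x2, m = m2, y = m2), x, m, y,
                  n_boot = 200, seed = 2)
  expect_lt(abs(fit2$c_prime), 1e-9)
  expect_equal(fit2$indirect, fit2$c, tolerance = 1e-9)
  # collinear mediator rejected
  expect_error(mediate(data.frame(x = x2, m = x2, y = m2), x, m, y,
                       n_boot = 10), "collinear")
  # bootstrap determinism
  fit3 <- mediate(data.frame(x, m, y), x, m, y, n_boot = 200, seed = 1)
  expect_identical(fit$ci_95, fit3$ci_95)
})

test_that("sample-size solver reproduces the a-priori N and its power bracket", {
  N <- anova_sample_size(k = 3, f = 0.25, alpha = 0.05, power = 0.80)
  expect_equal(N, 159L)
  expect_gte(anova_power(N, 3, 0.25), 0.80)
  expect_lt(anova_power(N - 3, 3, 0.25), 0.80)
  # monotone: larger effect, smaller or equal N; power increasing in N, f
  N_big <- anova_sample_size(k = 3, f = 0.4)
  expect_lte(N_big, N)
  Ns <- seq(30, 300, by = 30)
  pw <- vapply(Ns, anova_power, numeric(1), k = 3, f = 0.25)
  expect_true(all(diff(pw) > 0))
  pf_ <- vapply(c(0.1, 0.25, 0.4), function(f) anova_power(90, 3, f),
                numeric(1))
  expect_true(all(diff(pf_) > 0))
})

test_that("chi-squared independence matches the cellwise oracle", {
  even <- matrix(10, 2, 2)
  out <- chi_square_independence(even)
  expect_equal(out$chi2, 0)
  expect_equal(out$df, 1)
  # proportional margins -> 0
  prop <- outer(c(10, 20), c(3, 7)) / 10
  expect_lt(chi_square_independence(prop)$chi2, 1e-9)
  set.seed(56)
  tab <- matrix(rpois(6, 20) + 1, 2, 3)
  got <- chi_square_independence(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$chi2, sum((tab - E)^2 / E), tolerance = 1e-9)
  expect_equal(got$df, 2)
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)), "marginal")
})

test_that("type-I error of the one-way ANOVA is nominal under the null", {
  set.seed(57)
  rejections <- replicate(1000, {
    df <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
    one_way_anova(df, y, g)$p.value < 0.05
  })
  rate <- mean(rejections)
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 1000))
})
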
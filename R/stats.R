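#' One-way between-subjects ANOVA with partial eta-squared
#'
#' Standard between/within sums-of-squares decomposition via [stats::aov()];
#' effect size reported as partial eta-squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the response and the
#'   group factor.
#' @return Tibble with `effect`, `df1`, `df2`, `statistic`, `p.value`,
#'   `partial_eta_sq`.
#' @examples
#' df <- data.frame(y = rnorm(30), g = rep(letters[1:3], 10))
#' one_way_anova(df, y, g)
#' @export
one_way_anova <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  tab <- summary(aov(v ~ g))[[1]]
  ss_e <- tab["g", "Sum Sq"]
  ss_r <- tab["Residuals", "Sum Sq"]
  tibble::tibble(
    effect = "group",
    df1 = tab["g", "Df"], df2 = tab["Residuals", "Df"],
    statistic = tab["g", "F value"], p.value = tab["g", "Pr(>F)"],
    partial_eta_sq = ss_e / (ss_e + ss_r)
  )
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' One between-subjects factor and one or two within-subjects factors, in
#' long format, with subject as the error stratum for the between effect
#' and subject-by-within interactions as error strata for within effects —
#' the classical balanced split-plot decomposition via
#' `aov(y ~ between*w1*w2 + Error(subject/(w1*w2)))`. Requires every
#' subject to have all within-factor cells. No sphericity correction is
#' applied (two-level within factors need none).
#'
#' @param data Long-format data frame.
#' @param value Response column (tidy-eval).
#' @param between Between-subjects factor column.
#' @param within Character vector of 1 or 2 within-subjects factor columns.
#' @param subject Subject identifier column name (character).
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic`, `p.value`, `partial_eta_sq`.
#' @export
mixed_anova <- function(data, value, between, within, subject = "subject") {
  vq <- rlang::as_name(rlang::enquo(value))
  bq <- rlang::as_name(rlang::enquo(between))
  stopifnot(length(within) %in% 1:2, subject %in% names(data))
  df <- data.frame(
    .y = data[[vq]],
    .b = factor(data[[bq]]),
    .s = factor(data[[subject]])
  )
  for (i in seq_along(within)) df[[paste0(".w", i)]] <- factor(data[[within[i]]])
  wnames <- paste0(".w", seq_along(within))
  # balance check: every subject must have every within-cell exactly once
  cells <- table(df$.s, interaction(df[wnames]))
  if (any(cells != 1))
    stop("unbalanced design: every subject needs every within-factor cell ",
         "exactly once (listwise-delete incomplete subjects first)")
  rhs <- paste(c(".b", wnames), collapse = " * ")
  err <- paste0("Error(.s/(", paste(wnames, collapse = " * "), "))")
  form <- stats::as.formula(paste(".y ~", rhs, "+", err))
  fit <- aov(form, data = df)
  strata <- summary(fit)
  out <- list()
  for (st in strata) {
    tab <- st[[1]]
    rn <- trimws(rownames(tab))
    res <- which(rn == "Residuals")
    if (length(res) == 0) next
    ss_r <- tab[res, "Sum Sq"]; df_r <- tab[res, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), res)) {
      eff <- gsub(".b", bq, rn[i], fixed = TRUE)
      for (j in seq_along(within))
        eff <- gsub(paste0(".w", j), within[j], eff, fixed = TRUE)
      out[[length(out) + 1]] <- tibble::tibble(
        effect = gsub(":", " x ", eff),
        df1 = tab[i, "Df"], df2 = df_r,
        statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"],
        partial_eta_sq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_r)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Bonferroni adjustment for planned pairwise comparisons
#'
#' `p_adjusted = min(1, m * p_raw)` for `m` planned comparisons.
#'
#' @param p_raw Vector of raw p values.
#' @param m Number of comparisons in the family (default: length of
#'   `p_raw`).
#' @return Adjusted p values.
#' @export
bonferroni_pairwise <- function(p_raw, m = length(p_raw)) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p_raw)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with the
#' large-sample t approximation for the p value, via
#' [stats::cor.test()].
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval).
#' @return Tibble with `rho`, `p.value`, `n`.
#' @export
spearman_rho <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0)
    stop("constant input: Spearman's rho undefined")
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
                                         exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p.value = ct$p.value,
                 n = length(xv))
}

# closed-form OLS paths for the three mediation regressions
mediation_paths <- function(x, m, y) {
  n <- length(x)
  sx <- sum(x); sm <- sum(m); sy <- sum(y)
  vxx <- sum(x * x) - sx^2 / n
  vmm <- sum(m * m) - sm^2 / n
  vxm <- sum(x * m) - sx * sm / n
  vxy <- sum(x * y) - sx * sy / n
  vmy <- sum(m * y) - sm * sy / n
  a <- vxm / vxx
  c_tot <- vxy / vxx
  det2 <- vxx * vmm - vxm^2
  c_prime <- (vmm * vxy - vxm * vmy) / det2
  b <- (vxx * vmy - vxm * vxy) / det2
  c(a = a, b = b, c = c_tot, c_prime = c_prime)
}

#' Bootstrap mediation analysis
#'
#' Three ordinary-least-squares regressions — `M ~ X` (path a),
#' `Y ~ X + M` (paths c' and b), `Y ~ X` (total effect c) — with the
#' indirect effect `a * b` bootstrapped by resampling subjects with
#' replacement: percentile 2.5/97.5 confidence bounds and the bootstrap SD
#' as the standard error. The OLS identity `c = c' + a*b` holds exactly.
#'
#' @param data A data frame.
#' @param x,m,y Columns (tidy-eval): treatment (0/1 or continuous),
#'   mediator, outcome.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return An `ot_mediation` with paths `a`, `b`, `c`, `c_prime`,
#'   `indirect`, `se_boot`, `ci_95`, `n_boot`, `seed`, `n`.
#' @examples
#' d <- simulate_mediation_data(seed = 7)
#' mediate(d, x, m, y, n_boot = 200, seed = 1)
#' @export
mediate <- function(data, x, m, y, n_boot = 5000, seed = 1,
                    conf_level = 0.95) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  mv <- rlang::eval_tidy(rlang::enquo(m), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  n <- length(xv)
  stopifnot(length(mv) == n, length(yv) == n, n >= 4)
  if (sd(xv) == 0 || sd(mv) == 0) stop("x and m must vary")
  r_xm <- stats::cor(xv, mv)
  if (abs(r_xm) > 0.999)
    stop("mediator is collinear with treatment (|r| = ",
         round(abs(r_xm), 4), "); paths are not identifiable")
  paths <- mediation_paths(xv, mv, yv)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      p <- mediation_paths(xv[idx], mv[idx], yv[idx])
      p[["a"]] * p[["b"]]
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(
    a = unname(paths["a"]), b = unname(paths["b"]),
    c = unname(paths["c"]), c_prime = unname(paths["c_prime"]),
    indirect = unname(paths["a"] * paths["b"]),
    se_boot = sd(boot, na.rm = TRUE),
    ci_95 = ci, conf_level = conf_level,
    n_boot = as.integer(n_boot), seed = seed, n = n,
    boot = boot),
    class = "ot_mediation")
}

#' @export
print.ot_mediation <- function(x, ...) {
  cat("<ot_mediation> n = ", x$n, "\n",
      sprintf("  a = %.4g, b = %.4g, c = %.4g, c' = %.4g\n",
              x$a, x$b, x$c, x$c_prime),
      sprintf("  indirect = %.4g, se = %.3g, %g%% CI [%.4g, %.4g] (%d bootstraps)\n",
              x$indirect, x$se_boot, 100 * x$conf_level,
              x$ci_95[1], x$ci_95[2], x$n_boot), sep = "")
  invisible(x)
}

#' Tidy mediation paths
#' @param x An `ot_mediation`.
#' @param ... Unused.
#' @return Tibble with one row per path plus the indirect effect.
#' @export
tidy.ot_mediation <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "c_prime", "indirect"),
    estimate = c(x$a, x$b, x$c, x$c_prime, x$indirect),
    std.error = c(NA, NA, NA, NA, x$se_boot),
    conf.low = c(NA, NA, NA, NA, x$ci_95[1]),
    conf.high = c(NA, NA, NA, NA, x$ci_95[2])
  )
}

#' One-row mediation summary
#' @param x An `ot_mediation`.
#' @param ... Unused.
#' @return Tibble with the indirect effect, CI, and sample sizes.
#' @export
glance.ot_mediation <- function(x, ...) {
  tibble::tibble(indirect = x$indirect, se_boot = x$se_boot,
                 conf.low = x$ci_95[1], conf.high = x$ci_95[2],
                 n = x$n, n_boot = x$n_boot)
}

#' Bootstrap distribution plot for a mediation result
#' @param object An `ot_mediation`.
#' @param ... Unused.
#' @return A ggplot of the bootstrapped indirect effect.
#' @export
autoplot.ot_mediation <- function(object, ...) {
  df <- tibble::tibble(indirect = object$boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indirect)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$indirect, colour = "red") +
    ggplot2::geom_vline(xintercept = object$ci_95, linetype = "dashed") +
    ggplot2::labs(x = "bootstrapped indirect effect (a*b)", y = "count") +
    ggplot2::theme_minimal()
}

#' A-priori sample size for a one-way fixed-effects ANOVA
#'
#' Smallest total N, allocated equally across the `k` groups (so N is a
#' multiple of `k`), whose noncentral-F power reaches the target:
#' noncentrality `lambda = f^2 * N`, numerator df `k - 1`, denominator df
#' `N - k`.
#'
#' @param k Number of groups.
#' @param f Cohen's effect size f.
#' @param alpha Significance level.
#' @param power Target power.
#' @param n_cap Largest total N to consider before giving up.
#' @return Total sample size N (integer, multiple of `k`).
#' @examples
#' anova_sample_size(k = 3, f = 0.25) # 159
#' @export
anova_sample_size <- function(k = 3, f = 0.25, alpha = 0.05, power = 0.80,
                              n_cap = 100000) {
  stopifnot(k >= 2, f > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (N in seq(2 * k, n_cap, by = k)) {
    if (anova_power(N, k, f, alpha) >= power) return(as.integer(N))
  }
  stop("target power unreachable within N <= ", n_cap)
}

#' Power of the one-way fixed-effects ANOVA at a given total N
#' @param N Total sample size.
#' @param k Number of groups.
#' @param f Cohen's effect size f.
#' @param alpha Significance level.
#' @return Power from the noncentral F distribution (`ncp = f^2 * N`).
#' @export
anova_power <- function(N, k = 3, f = 0.25, alpha = 0.05) {
  1 - pf(qf(1 - alpha, k - 1, N - k), k - 1, N - k, ncp = f^2 * N)
}

#' Pearson chi-squared test of independence
#'
#' @param contingency_table Matrix of nonnegative counts (>= 2x2).
#' @return Tibble with `chi2`, `df`, `p.value`.
#' @export
chi_square_independence <- function(contingency_table) {
  tab <- as.matrix(contingency_table)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p.value = ct$p.value)
}

#' Exclusion accounting for an enrolled roster
#'
#' @param roster Data frame with an `exclusion_reason` column
#'   (`"none"`, `"incomplete"`, `"technical"`), e.g. the `subjects` tibble
#'   of an [simulate_cohort()] cohort.
#' @return Tibble with `enrolled`, `analyzed` and one count column per
#'   exclusion reason.
#' @export
exclusion_accounting <- function(roster) {
  reasons <- roster$exclusion_reason
  known <- c("none", "incomplete", "technical")
  bad <- setdiff(unique(reasons), known)
  if (length(bad) > 0)
    stop("unknown exclusion reason(s): ", paste(bad, collapse = ", "))
  tally <- table(factor(reasons, levels = known))
  tibble::tibble(enrolled = length(reasons),
                 analyzed = as.integer(tally["none"]),
                 incomplete = as.integer(tally["incomplete"]),
                 technical = as.integer(tally["technical"]))
}
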
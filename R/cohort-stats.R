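#' Power of a two-sample, two-tailed t test
#'
#' Exact power via the noncentral t distribution with `df = 2n - 2` and
#' noncentrality `d * sqrt(n / 2)` for equal group sizes `n` and
#' standardized effect size `d` (Cohen's d).
#'
#' @param n Sample size per group (>= 2).
#' @param effect_size Cohen's d (>= 0).
#' @param alpha Two-tailed significance level.
#' @return Power (probability of rejecting at `alpha`).
#' @export
#' @examples
#' achieved_power(24, 1.06)
achieved_power <- function(n, effect_size, alpha = 0.05) {
  stopifnot(n >= 2, effect_size >= 0, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  ncp <- effect_size * sqrt(n / 2)
  crit <- qt(1 - alpha / 2, df)
  (1 - pt(crit, df, ncp)) + pt(-crit, df, ncp)
}

#' Required per-group sample size for a target power
#'
#' Smallest integer `n` per group for which the two-sample, two-tailed
#' noncentral-t power ([achieved_power()]) reaches the target.  The search
#' increments `n` from 2, matching the behavior of dedicated power software
#' (power is monotone in `n`).
#'
#' @param effect_size Cohen's d, > 0.
#' @param alpha Two-tailed significance level.
#' @param power Target power in (0, 1).
#' @param n_max Search cap.
#' @return Integer sample size per group.
#' @export
#' @examples
#' required_sample_size(1.06, alpha = 0.05, power = 0.95)
required_sample_size <- function(effect_size, alpha = 0.05, power = 0.95,
                                 n_max = 1e6) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (effect_size <= 0)
    stop("no finite sample size reaches the target power when d = 0")
  n <- 2L
  while (achieved_power(n, effect_size, alpha) < power) {
    n <- n + 1L
    if (n > n_max) stop("sample-size search exceeded n_max = ", n_max)
  }
  n
}

#' Normality screen (Lilliefors-corrected Kolmogorov–Smirnov)
#'
#' Distribution parameters are estimated from the data, so the
#' Kolmogorov–Smirnov screen uses the Lilliefors correction
#' ([nortest::lillie.test()]).  A degenerate (constant) sample is reported
#' as non-normal.
#'
#' @param x Numeric sample, n >= 5.
#' @param alpha Significance level of the screen.
#' @return `TRUE` if normality is not rejected at `alpha`.
#' @export
normality_flag <- function(x, alpha = 0.05) {
  stopifnot(is.numeric(x))
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("normality screen needs at least 5 observations")
  if (sd(x) == 0) return(FALSE)
  nortest::lillie.test(x)$p.value >= alpha
}

comparison_result <- function(test, statistic, p, adjusted = NA_real_,
                              alpha = 0.05) {
  structure(list(test = test, statistic = as.numeric(statistic),
                 p_value = as.numeric(p),
                 p_adjusted = as.numeric(adjusted),
                 significant = is.finite(p) && p < alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s%s\n", x$test, x$statistic,
              x$p_value,
              if (is.finite(x$p_adjusted))
                sprintf(" (adjusted %.4g)", x$p_adjusted) else "",
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Paired symptomatic-vs-asymptomatic comparison
#'
#' Paired t test when both samples pass the normality screen
#' ([normality_flag()]), otherwise the Wilcoxon signed-rank test — the valid
#' nonparametric test for two related samples.  Identical samples (all
#' paired differences zero) are reported with p = 1 by convention.
#'
#' @param symptomatic,asymptomatic Equal-length numeric vectors (n >= 5),
#'   paired by subject.
#' @param alpha Significance level.
#' @param method `"auto"` (normality-screened, the default), or force
#'   `"t"` / `"wilcoxon"`.
#' @return A `comparison_result`.
#' @export
paired_compare <- function(symptomatic, asymptomatic, alpha = 0.05,
                           method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(symptomatic) != length(asymptomatic))
    stop("paired samples must have equal length")
  stopifnot(length(symptomatic) >= 5)
  d <- symptomatic - asymptomatic
  if (all(d == 0))
    return(comparison_result("Wilcoxon signed-rank", 0, 1, alpha = alpha))
  parametric <- switch(method,
    auto = normality_flag(symptomatic, alpha) &&
           normality_flag(asymptomatic, alpha),
    t = TRUE, wilcoxon = FALSE)
  if (parametric) {
    tt <- t.test(symptomatic, asymptomatic, paired = TRUE)
    comparison_result("paired t", tt$statistic, tt$p.value, alpha = alpha)
  } else {
    wt <- suppressWarnings(
      wilcox.test(symptomatic, asymptomatic, paired = TRUE))
    comparison_result("Wilcoxon signed-rank", wt$statistic, wt$p.value,
                      alpha = alpha)
  }
}

#' Three-group comparison with Bonferroni pairwise tests
#'
#' One-way ANOVA when every group passes the normality screen, otherwise the
#' Kruskal–Wallis rank-sum test; pairwise comparisons (t or Wilcoxon
#' rank-sum accordingly) have their p-values multiplied by 3 (Bonferroni)
#' and capped at 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of the same length with 3 levels,
#'   each n >= 5.
#' @param alpha Significance level.
#' @param method `"auto"` (normality-screened, the default), or force
#'   `"anova"` / `"kruskal"`.
#' @return List with `omnibus` (a `comparison_result`) and `pairwise`
#'   (data.frame: `group1`, `group2`, `p_value`, `p_adjusted`,
#'   `significant`).
#' @export
three_group_compare <- function(values, groups, alpha = 0.05,
                                method = c("auto", "anova", "kruskal")) {
  method <- match.arg(method)
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 3)
    stop("three_group_compare requires 3 groups, got ", nlevels(groups))
  split_vals <- split(values, groups)
  stopifnot(all(vapply(split_vals, length, 1L) >= 5))
  normal <- switch(method,
    auto = all(vapply(split_vals, normality_flag, TRUE, alpha = alpha)),
    anova = TRUE, kruskal = FALSE)
  if (normal) {
    fit <- aov(values ~ groups)
    an <- anova(fit)
    omni <- comparison_result("one-way ANOVA", an$`F value`[1], an$`Pr(>F)`[1],
                              alpha = alpha)
  } else {
    kw <- kruskal.test(values, groups)
    omni <- comparison_result("Kruskal-Wallis", kw$statistic, kw$p.value,
                              alpha = alpha)
  }
  pairs <- utils::combn(levels(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- split_vals[[pairs[1, j]]]; b <- split_vals[[pairs[2, j]]]
    p <- if (normal) t.test(a, b)$p.value
         else suppressWarnings(wilcox.test(a, b)$p.value)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               p_value = p, p_adjusted = min(1, 3 * p),
               significant = min(1, 3 * p) < alpha,
               stringsAsFactors = FALSE)
  }))
  list(omnibus = omni, pairwise = pw)
}

#' Absolute bilateral-difference feature vector of one subject
#'
#' For each muscle and each of the four SEMG parameters, the absolute
#' difference between the two sides: symptomatic minus asymptomatic for
#' patients, left minus right for healthy subjects (the absolute value makes
#' the healthy labeling irrelevant).
#'
#' @param record A `subject_record` (see [extract_subject()]).
#' @return One-row `data.frame` with `subject_id`, `group` and the eight
#'   [diff_feature_names()] columns (all >= 0).
#' @export
bilateral_difference <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  ft <- record$features
  if (nrow(ft) != 4 || !all(c("TA", "LG") %in% ft$muscle))
    stop("subject record must contain all four muscle/side feature sets")
  side_a <- if (record$symptomatic_side %in% c("left", "right"))
    record$symptomatic_side else "left"
  side_b <- setdiff(c("left", "right"), side_a)
  out <- list(subject_id = record$id, group = record$group)
  params <- c(RMSpeak = "rms_peak", RMSpeaktime = "rms_peak_time",
              MPF = "mpf", MF = "mf")
  for (m in c("TA", "LG")) for (k in seq_along(params)) {
    a <- ft[ft$muscle == m & ft$side == side_a, params[k]]
    b <- ft[ft$muscle == m & ft$side == side_b, params[k]]
    if (length(a) != 1 || length(b) != 1)
      stop("missing ", m, " feature set for one side")
    out[[paste0(m, "_", names(params)[k], "_diff")]] <- abs(a - b)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Per-group summary of a feature
#'
#' @param values Numeric vector.
#' @param groups Factor of group labels.
#' @return `data.frame` with one row per group: `n`, `mean`, `se`, `median`,
#'   `q1`, `q3`, `normal` (normality-screen flag) and `display` — the value
#'   formatted as "mean ± SE" when normal and "median (q1, q3)" otherwise.
#' @export
group_summary <- function(values, groups) {
  groups <- droplevels(factor(groups))
  do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    nrm <- if (length(v) >= 5) normality_flag(v) else NA
    data.frame(group = g, n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)),
               median = q[2], q1 = q[1], q3 = q[3], normal = nrm,
               display = if (isTRUE(nrm))
                 sprintf("%.2f ± %.2f", mean(v), sd(v) / sqrt(length(v)))
               else sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3]),
               stringsAsFactors = FALSE)
  }))
}

#' Group-comparison table over the eight difference features
#'
#' For each difference feature: per-group summaries, the omnibus three-group
#' test and the Bonferroni-adjusted pairwise pattern — the feature-table
#' analog of a published cohort comparison.
#'
#' @param cohort Feature cohort `data.frame` (`group` + the eight
#'   [diff_feature_names()] columns).
#' @param alpha Significance level.
#' @return `data.frame`, one row per feature, with per-group `display`
#'   columns, omnibus test name and p-value, and one adjusted-p column per
#'   group pair.
#' @export
diff_group_table <- function(cohort, alpha = 0.05) {
  stopifnot(all(diff_feature_names() %in% names(cohort)))
  do.call(rbind, lapply(diff_feature_names(), function(ft) {
    gs <- group_summary(cohort[[ft]], cohort$group)
    cmp <- three_group_compare(cohort[[ft]], cohort$group, alpha)
    row <- data.frame(feature = ft, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(gs))) row[[gs$group[i]]] <- gs$display[i]
    row$test <- cmp$omnibus$test
    row$p_value <- cmp$omnibus$p_value
    for (i in seq_len(nrow(cmp$pairwise)))
      row[[paste0("p_adj_", cmp$pairwise$group1[i], "_vs_",
                  cmp$pairwise$group2[i])]] <- cmp$pairwise$p_adjusted[i]
    row
  }))
}

#' Paired side-comparison table for one patient group
#'
#' Symptomatic vs asymptomatic side for each muscle and SEMG parameter —
#' the per-side analog of the published patient tables.
#'
#' @param records List of `subject_record`s, all of the same patient group.
#' @param alpha Significance level.
#' @return `data.frame` with one row per muscle/parameter: summary displays
#'   for both sides, test name and p-value.
#' @export
paired_side_table <- function(records, alpha = 0.05) {
  stopifnot(length(records) >= 5)
  params <- c(rms_peak = "RMS-peak", rms_peak_time = "RMS-peak time",
              mpf = "MPF", mf = "MF")
  side_of <- function(r, m, s) {
    r$features[r$features$muscle == m & r$features$side == s, ]
  }
  do.call(rbind, lapply(c("TA", "LG"), function(m) {
    do.call(rbind, lapply(names(params), function(p) {
      symp <- vapply(records, function(r)
        side_of(r, m, r$symptomatic_side)[[p]], 1)
      asym <- vapply(records, function(r)
        side_of(r, m, setdiff(c("left", "right"), r$symptomatic_side))[[p]], 1)
      cmp <- paired_compare(symp, asym, alpha)
      data.frame(muscle = m, parameter = params[[p]],
                 symptomatic = group_summary(symp, rep("s", length(symp)))$display,
                 asymptomatic = group_summary(asym, rep("a", length(asym)))$display,
                 test = cmp$test, p_value = cmp$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
}
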
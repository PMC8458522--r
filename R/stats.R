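#' Summarise a set of AUCs
#'
#' Mean, sample SD (n - 1 denominator) and a normal-theory 95% interval
#' `mean +/- 1.96 * SD / sqrt(n)`. The z multiplier (rather than a
#' t-quantile) is the convention used when AUC distributions over many
#' resampled models are reported.
#'
#' @param aucs Numeric vector, length >= 2.
#' @param label Condition label carried into the output.
#' @return One-row tibble: `condition`, `n_models`, `mean_auc`, `sd_auc`,
#'   `ci_low`, `ci_high`.
#' @export
summarize_aucs <- function(aucs, label = "auc") {
  n <- length(aucs)
  if (n < 2) abort("Need at least 2 AUCs to summarise", class = "cslvr_stats_error")
  m <- mean(aucs)
  s <- sd(aucs)
  half <- 1.96 * s / sqrt(n)
  tibble(condition = label, n_models = n, mean_auc = m, sd_auc = s,
         ci_low = m - half, ci_high = m + half)
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value; usable straight from published means and SDs.
#'
#' @param mean1,sd1,n1 First group's moments and size.
#' @param mean2,sd2,n2 Second group's moments and size.
#' @return One-row tibble: `t`, `df`, `p_two_sided`.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("Both groups need n >= 2", class = "cslvr_stats_error")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    abort("SDs must be >= 0 and not both 0", class = "cslvr_stats_error")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  tibble(t = t_stat, df = df, p_two_sided = p)
}

#' Welch t-test from two samples
#'
#' Identical to [welch_from_summary()] applied to the sample moments.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p_two_sided`.
#' @export
welch_from_samples <- function(x, y) {
  welch_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}
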
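#' Assign persons to score quintiles
#'
#' Persons are ranked by ascending score (quintile 1 = lowest predicted
#' risk), rank ties broken by stable person-ID order, and the ranking cut
#' into five contiguous blocks whose sizes differ by at most one, larger
#' blocks first. Any monotone transformation of the scores leaves the
#' assignment unchanged.
#'
#' @param scores Tibble with `person_id` and `score` (>= 5 rows), or a named
#'   numeric vector.
#' @param n_quantiles Number of blocks (default 5; deciles etc. are
#'   accepted but only quintiles are exercised against published tables).
#' @return Tibble `person_id`, `score`, `quintile`.
#' @export
assign_quintiles <- function(scores, n_quantiles = 5L) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble(person_id = names(scores), score = as.numeric(scores))
  }
  n <- nrow(scores)
  if (n < n_quantiles) {
    abort(sprintf("Need at least %d persons", n_quantiles), class = "cslvr_stats_error")
  }
  ord <- order(scores$score, scores$person_id)
  sizes <- block_sizes(n, n_quantiles)
  q <- rep.int(seq_len(n_quantiles), times = sizes)
  out <- scores[ord, c("person_id", "score")]
  out$quintile <- q
  out |> arrange(.data$person_id)
}

#' Quintile odds ratio
#'
#' The within-quintile case:control odds divided by the cohort-wide odds:
#' `(n_cases_q / n_controls_q) / (total_cases / total_controls)`. Under a
#' balanced 1:1 design this equals the raw within-quintile odds.
#'
#' @param n_cases_q,n_controls_q Counts inside the quintile (positive).
#' @param total_cases,total_controls Cohort totals.
#' @return The odds ratio.
#' @export
quintile_odds_ratio <- function(n_cases_q, n_controls_q, total_cases, total_controls) {
  if (any(c(n_cases_q, n_controls_q, total_cases, total_controls) <= 0)) {
    abort("All counts must be positive (see or_confidence_interval for the zero-cell flag)",
          class = "cslvr_stats_error")
  }
  (n_cases_q / n_controls_q) / (total_cases / total_controls)
}

#' Wald confidence interval for a quintile odds ratio
#'
#' Normal-theory interval on the log odds ratio with
#' `SE = sqrt(1/n_cases_q + 1/n_controls_q)`, exponentiated. With
#' `correct = TRUE` a 0.5 continuity correction is added to both cells,
#' allowing zero counts.
#'
#' @param n_cases_q,n_controls_q Quintile cell counts.
#' @param total_cases,total_controls Cohort totals (for the OR point value).
#' @param level Coverage (default 0.95).
#' @param correct Apply the 0.5 continuity correction?
#' @return One-row tibble: `or`, `ci_low`, `ci_high`.
#' @export
or_confidence_interval <- function(n_cases_q, n_controls_q,
                                   total_cases = NULL, total_controls = NULL,
                                   level = 0.95, correct = FALSE) {
  a <- n_cases_q
  b <- n_controls_q
  if (correct) {
    a <- a + 0.5
    b <- b + 0.5
  } else if (a <= 0 || b <= 0) {
    abort("Zero cell; set correct = TRUE for a continuity correction",
          class = "cslvr_stats_error")
  }
  if (is.null(total_cases)) total_cases <- 1
  if (is.null(total_controls)) total_controls <- 1
  or <- (a / b) / (total_cases / total_controls)
  se <- sqrt(1 / a + 1 / b)
  z <- qnorm(1 - (1 - level) / 2)
  tibble(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

#' Build the quintile odds-ratio table
#'
#' Stratifies scored persons into quintiles and reports, per quintile, the
#' control and case counts, the odds ratio relative to the cohort-wide
#' odds, and its Wald interval.
#'
#' @param scores Tibble with `person_id`, `score`, `label` (1 = case).
#' @param level CI coverage.
#' @param correct Apply the 0.5 continuity correction (required when a
#'   quintile holds no cases or no controls; an uncorrected zero cell
#'   errors).
#' @return A `cslv_quintiles` tibble: `quintile`, `n_controls`, `n_cases`,
#'   `odds_ratio`, `count`, `ci_low`, `ci_high`.
#' @export
quintile_table <- function(scores, level = 0.95, correct = FALSE) {
  qa <- assign_quintiles(scores)
  joined <- qa |> left_join(scores[c("person_id", "label")], by = "person_id")
  tot_cases <- sum(joined$label == 1L)
  tot_controls <- sum(joined$label == 0L)
  out <- joined |>
    group_by(.data$quintile) |>
    summarise(n_controls = sum(.data$label == 0L),
              n_cases = sum(.data$label == 1L), .groups = "drop") |>
    mutate(count = .data$n_controls + .data$n_cases)
  if (!correct && any(out$n_cases == 0 | out$n_controls == 0)) {
    abort("Zero cell; set correct = TRUE for a continuity correction",
          class = "cslvr_stats_error")
  }
  ci <- purrr::map2(out$n_cases, out$n_controls, or_confidence_interval,
                    total_cases = tot_cases, total_controls = tot_controls,
                    level = level, correct = correct)
  out <- dplyr::bind_cols(out, bind_rows(ci) |> dplyr::rename(odds_ratio = "or"))
  out <- out[c("quintile", "n_controls", "n_cases", "odds_ratio", "count",
               "ci_low", "ci_high")]
  class(out) <- c("cslv_quintiles", class(out))
  out
}
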
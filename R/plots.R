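#' Boxplot of cross-validated AUCs by learner and split resolution
#'
#' One box per learner, faceted by split count — the standard way to compare
#' learner families across replicated matched cohorts.
#'
#' @param run A `cslv_run`.
#' @return A ggplot object.
#' @export
plot_auc_distribution <- function(run) {
  ggplot2::ggplot(run$results,
                  ggplot2::aes(x = .data$learner, y = .data$cv_auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$k), labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Cross-validated AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Variable-importance heatmap
#'
#' Models (replicate x learner) on the y axis, features on the x axis, fill
#' = max-normalized importance; values near 1 mark the features a model
#' leaned on.
#'
#' @param run A `cslv_run`.
#' @param k Split resolution (default: finest in the run).
#' @return A ggplot object.
#' @export
plot_importance_heatmap <- function(run, k = NULL) {
  k <- k %||% max(run$importances$k)
  dat <- run$importances |>
    filter(.data$k == !!k) |>
    mutate(model = paste0(.data$learner, "#", .data$replicate_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$feature_name, y = .data$model,
                                    fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Quintile odds-ratio plot
#'
#' Point estimates with Wald intervals against the null line at OR = 1.
#'
#' @param object A `cslv_quintiles` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cslv_quintiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$quintile), y = .data$odds_ratio)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Score quintile", y = "Odds ratio (vs cohort odds)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_auc_distribution
#' @param object A `cslv_run`.
#' @param ... Unused.
#' @export
autoplot.cslv_run <- function(object, ...) plot_auc_distribution(object)

#' @rdname tidy
#' @export
tidy.cslv_quintiles <- function(x, ...) as_tibble(x)
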
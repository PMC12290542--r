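#' Plot a ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Group comparison dot plot
#'
#' Per-subject bilateral means with cohort averages, one panel per metric,
#' for a chosen region.
#'
#' @param cohort Long cohort tibble.
#' @param region Region to plot.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(cohort, region = "CA4/DG") {
  bil <- bilateral_mean(cohort)
  meta <- unique(cohort[, c("subject_id", "group")])
  df <- dplyr::left_join(bil[bil$region == region, ], meta,
                         by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "bar", fill = "grey80",
                          width = 0.6) +
    ggplot2::geom_jitter(width = 0.1, size = 1, colour = "black") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = region) +
    ggplot2::theme_minimal()
}

#' Asymmetry index dot plot
#'
#' Per-subject signed asymmetry indices (contra minus ipsi, percent) in the
#' suspected-unilateral subgroup, one column per metric.
#'
#' @param cohort Long cohort tibble.
#' @param region Region to plot.
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(cohort, region = "CA4/DG") {
  uni <- cohort[cohort$suspected_side %in% c("left", "right") &
                  cohort$region == region, ]
  uni$side_rel <- ifelse(uni$hemisphere == uni$suspected_side,
                         "ipsi", "contra")
  wide <- tidyr::pivot_wider(
    uni[, c("subject_id", "metric", "side_rel", "value")],
    names_from = "side_rel", values_from = "value")
  wide$asymmetry <- asymmetry_index(wide$contra, wide$ipsi)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$metric, y = .data$asymmetry)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.08, size = 1.5, colour = "#2166ac") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Asymmetry index (%)", title = region) +
    ggplot2::theme_minimal()
}

#' Significance overview of an analysis
#'
#' Tile map of -log10 p-values of the group comparisons, marking cells that
#' pass their Bonferroni-corrected threshold.
#'
#' @param object A `mufa_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mufa_analysis <- function(object, ...) {
  df <- object$group_stats
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$region,
                                   fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
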
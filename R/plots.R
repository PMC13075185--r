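#' Violin plot of per-trait STI distributions
#'
#' @param sti STI tibble from [compute_sti()].
#' @return A ggplot object, facetted by stage.
#' @export
plot_sti <- function(sti) {
  sti |>
    dplyr::filter(is.finite(.data$sti)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$trait, y = .data$sti)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red3") +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Stress tolerance index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Manhattan plot of an association scan
#'
#' @param scan Per-marker scan tibble from [association_scan()] or the
#'   `scan` element of [scan_traits()].
#' @param threshold Optional genome-wide p-value threshold drawn as a line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, threshold = NULL) {
  scan <- dplyr::filter(scan, !is.na(.data$p_value))
  scan$chrom <- factor(scan$chrom, levels = unique(scan$chrom))
  p <- ggplot2::ggplot(scan, ggplot2::aes(
    x = .data$pos, y = -log10(.data$p_value), colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(
      if ("trait" %in% names(scan)) trait ~ chrom else . ~ chrom,
      scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = 2, colour = "red3")
  }
  p
}

#' Cross-stage transition flow plot
#'
#' Segment-based rendering of class transitions between two stages (an
#' alluvial-style view without extra dependencies).
#'
#' @param transitions Tibble from [cross_stage()]`$transitions`.
#' @return A ggplot object.
#' @export
plot_cross_stage <- function(transitions) {
  counts <- dplyr::count(transitions, .data$class_stage1, .data$class_stage2,
                         .data$direction)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = 1, xend = 2,
    y = as.integer(.data$class_stage1),
    yend = as.integer(.data$class_stage2),
    linewidth = .data$n, colour = .data$direction)) +
    ggplot2::geom_segment(alpha = 0.7) +
    ggplot2::scale_y_continuous(breaks = 1:5, labels = tolerance_levels()) +
    ggplot2::scale_x_continuous(breaks = c(1, 2),
                                labels = c("stage 1", "stage 2"),
                                limits = c(0.8, 2.2)) +
    ggplot2::labs(x = NULL, y = "Tolerance class", linewidth = "genotypes") +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted scatter for a prediction report
#'
#' @param report Tibble from [prediction_report()].
#' @return A ggplot object.
#' @export
plot_predictions <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$observed,
                                       y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "Observed AMFV", y = "Predicted score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.salt_cv <- function(object, ...) {
  ggplot2::ggplot(object$cv_table, ggplot2::aes(
    x = log10(.data$lambda), y = .data$cvm,
    colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$lambda_min), linetype = 2) +
    ggplot2::labs(x = expression(log[10](lambda)), y = "CV MSE",
                  colour = expression(alpha)) +
    ggplot2::theme_minimal()
}
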
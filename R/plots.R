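#' Barcode rank plot (knee plot)
#'
#' Log-log plot of barcode read counts against rank; real cells form the
#' high plateau, error barcodes the tail, and the knee separates them.
#'
#' @param knee a tibble from [knee_curve()].
#' @return a ggplot object.
#' @export
plot_knee <- function(knee) {
  ggplot2::ggplot(knee, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "read count",
                  title = "Barcode rank curve") +
    ggplot2::theme_minimal()
}

#' Confusion heatmap of a scored clustering
#'
#' @param object an `accuracy_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.accuracy_report <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$cluster, y = .data$sub,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "cluster", y = "true subcategory", fill = "cells",
                  title = sprintf("accuracy: major %.3f / sub %.3f",
                                  object$accuracy_major,
                                  object$accuracy_sub)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Accuracy boxplots over a benchmark grid
#'
#' @param object a `benchmark_result`.
#' @param x grid axis on the x scale (default `"clustering"`).
#' @param colour grid axis mapped to colour (default `"normalization"`).
#' @param ... unused.
#' @return a ggplot object (major and sub accuracy in facets).
#' @export
autoplot.benchmark_result <- function(object, x = "clustering",
                                      colour = "normalization", ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(as_tibble(object), is.na(.data$error)),
    c("accuracy_major", "accuracy_sub"),
    names_to = "level", values_to = "accuracy", names_prefix = "accuracy_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$accuracy,
                                     colour = .data[[colour]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~level) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
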
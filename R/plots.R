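# ggplot2 views of the package's result objects.

#' Plot a peak list as a stick spectrum
#'
#' @param peaks Tibble with `mz` and `intensity`.
#' @param title Optional plot title.
#' @return A ggplot.
#' @export
plot_spectrum <- function(peaks, title = NULL) {
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::labs(x = "m/z (Da)", y = "relative intensity", title = title) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.msvae_history <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"epoch", names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value, colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.msvae_pfi <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$importance)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "performance drop under permutation", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.msvae_correlation_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$factor, y = factor(.data$latent_index), fill = .data$mean_r
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "latent variable", fill = "mean r") +
    ggplot2::theme_minimal()
}

#' Plot partition-level correlation distributions
#'
#' Histograms of partition Pearson coefficients per factor x latent pair,
#' the distributional view used to judge consistency of the two-step
#' analysis.
#'
#' @param cells Correlation cells from [correlate_partitions()].
#' @return A ggplot faceted by factor (rows) and latent index (columns).
#' @export
plot_correlation_cells <- function(cells) {
  df <- dplyr::filter(cells, .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 21, boundary = 0) +
    ggplot2::facet_grid(factor ~ latent_index, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "partition Pearson r", y = "partitions") +
    ggplot2::theme_minimal()
}
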
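#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sinogram or slice as an intensity raster
#'
#' @param x A [sinogram()] or plain matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_image <- function(x, title = NULL) {
  ang <- if (is_sinogram(x)) angles(x) else seq_len(nrow(x))
  m <- if (is_sinogram(x)) sino_data(x) else as.matrix(x)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(t(m))[(df$row - 1) * ncol(m) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = if (is_sinogram(x)) "detector pixel" else "column",
                  y = if (is_sinogram(x)) "projection (row)" else "row",
                  fill = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.train_fit
#' @param object A `train_fit`.
#' @export
autoplot.train_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL,
                  title = "Training and validation loss") +
    ggplot2::theme_minimal()
}

#' @rdname evaluate
#' @param object An `evaluation_report`.
#' @param metric Column of the per-sample table to aggregate
#'   (`"psnr_sino"`, `"ssim_sino"`, `"psnr_slice"` or `"ssim_slice"`).
#' @export
autoplot.evaluation_report <- function(object, metric = "psnr_sino", ...) {
  stopifnot(metric %in% c("psnr_sino", "ssim_sino", "psnr_slice", "ssim_slice"))
  df <- object$samples |>
    dplyr::filter(is.na(.data$error), is.finite(.data[[metric]])) |>
    dplyr::group_by(.data$method, .data$degradation_bin) |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     sd = stats::sd(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degradation_bin, y = .data$mean,
                                   colour = .data$method,
                                   group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "artifact severity bin (degradation PSNR)",
                  y = metric, colour = NULL,
                  title = "Correction quality by artifact severity") +
    ggplot2::theme_minimal()
}
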
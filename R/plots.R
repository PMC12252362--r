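#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.projection_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(color = "#8B0000") +
    ggplot2::labs(
      x = if (attr(object, "axis") == "collapse_rows") "column" else "row",
      y = "summed gray value",
      title = "Directional projection curve"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cwt_result <- function(object, per_scale = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$value))
  if (per_scale) {
    ps <- attr(object, "per_scale")
    long <- tibble::tibble(
      index = rep(seq_len(ncol(ps)), each = nrow(ps)),
      scale = factor(rep(attr(object, "scales"), ncol(ps))),
      value = as.vector(ps)
    )
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(group = .data$scale, color = .data$scale),
      alpha = 0.5
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "orange") +
    ggplot2::labs(x = "position", y = "wavelet coefficient",
                  title = "Mexican Hat CWT detection curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quant_result <- function(object, ...) {
  surf <- object$surface
  df <- tibble::tibble(
    y = rep(object$rows$y, times = ncol(surf)),
    x = rep(object$scan_left + seq_len(ncol(surf)) - 1L, each = nrow(surf)),
    value = as.vector(surf)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(
      x = "column", y = "row", fill = "signal",
      title = sprintf("Background-subtracted signal (avePix = %.3g)", object$ave_pix)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fourpl <- function(object, n_grid = 200, ...) {
  rng <- range(object$data$dose)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_grid))
  curve_df <- tibble::tibble(dose = grid, signal = predict(object, grid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$signal)) +
    ggplot2::geom_line(data = curve_df, color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "signal",
                  title = sprintf("4PL calibration (R² = %.4f)", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a strip image with detected ROIs
#'
#' @param image An [lfa_image].
#' @param rois Optional [extract_rois()] tibble to overlay.
#' @return A ggplot object.
#' @export
plot_strip <- function(image, rois = NULL) {
  d <- image$data
  df <- tibble::tibble(
    y = rep(seq_len(nrow(d)), times = ncol(d)),
    x = rep(seq_len(ncol(d)), each = nrow(d)),
    gray = as.vector(d)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "column", y = "row", fill = "gray")
  if (!is.null(rois) && nrow(rois)) {
    p <- p + ggplot2::geom_rect(
      data = rois, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$x_left, xmax = .data$x_right,
                   ymin = .data$top, ymax = .data$down),
      color = "cyan", fill = NA, linewidth = 0.4
    )
  }
  p
}
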
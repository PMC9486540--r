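#' Plot a fitted dose-response curve
#'
#' Points on a log-dose axis with the fitted four-parameter logistic
#' overlaid and the inflection (`x_half`, the EC50/IC50) marked.
#'
#' @param object A `fit_4pl` object.
#' @param n_curve Number of points used to draw the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fit_4pl
#' @export
autoplot.fit_4pl <- function(object, n_curve = 200, ...) {
  cf <- object$coefficients
  xr <- range(object$data$x)
  grid <- tibble(x = exp(seq(log(xr[1]), log(xr[2]), length.out = n_curve)))
  grid$y <- predict_4pl(cf, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = cf[["x_half"]], linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response",
                  subtitle = sprintf("x_half = %.3g, hill = %.2f",
                                     cf[["x_half"]], cf[["hill"]])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-patient fold changes coloured by assigned category
#'
#' AChR fold change against MAC fold change with the classification band
#' boundaries drawn, one point per patient.
#'
#' @param readouts Per-patient tibble from [stratify_cohort()].
#' @return A ggplot object.
#' @export
plot_cohort <- function(readouts) {
  stopifnot(all(c("achr_fold", "mac_fold", "category") %in% names(readouts)))
  ggplot2::ggplot(readouts,
                  ggplot2::aes(x = .data$achr_fold, y = .data$mac_fold,
                               colour = factor(.data$category))) +
    ggplot2::geom_vline(xintercept = c(0.3, 0.6, 0.8, 1), colour = "grey85") +
    ggplot2::geom_hline(yintercept = c(1, 1.3, 1.8, 2.3, 3.5),
                        colour = "grey85") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "AChR fold change vs NHS",
                  y = "MAC fold change vs NHS", colour = "category") +
    ggplot2::theme_minimal()
}

#' Display one channel of an imaging field
#'
#' Raster view of a channel with optional nucleus-centroid overlay,
#' intended for quick inspection of synthetic fields.
#'
#' @param field An `image_field`.
#' @param channel Channel role to display.
#' @param truth Optional ground-truth tibble from [generate_field()];
#'   nucleus centroids are overlaid when given.
#' @param downsample Keep every k-th pixel (default 2) to keep the plot
#'   light.
#' @return A ggplot object.
#' @export
plot_field <- function(field, channel = "achr", truth = NULL,
                       downsample = 2L) {
  x <- get_channel(field, channel)
  ri <- seq(1L, nrow(x), by = downsample)
  ci <- seq(1L, ncol(x), by = downsample)
  df <- tidyr::expand_grid(row = ri, col = ci)
  df$value <- x[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(channel, " channel"), fill = "intensity") +
    ggplot2::theme_void()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(
      data = truth,
      ggplot2::aes(x = .data$nucleus_col, y = .data$nucleus_row),
      inherit.aes = FALSE, colour = "red", shape = 3, size = 0.8
    )
  }
  p
}
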
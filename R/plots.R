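#' Plot a maximum intensity projection
#'
#' @param volume An [image_volume()] or `vesselness_map`.
#' @param axis Projection axis (1-3).
#' @return A ggplot object.
#' @export
plot_mip <- function(volume, axis = 2) {
  if (inherits(volume, "vesselness_map")) {
    volume <- image_volume(volume$response, volume$spacing, volume$origin,
                           volume$orientation)
  }
  mip <- maximum_intensity_projection(volume, axis)
  df <- tidyr::expand_grid(i = seq_len(nrow(mip)), j = seq_len(ncol(mip)))
  df$intensity <- mip[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "max\nintensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vesselness_map <- function(object, axis = 2, ...) {
  plot_mip(object, axis) + ggplot2::ggtitle("Vesselness (MIP)")
}

#' @export
autoplot.accuracy_summary <- function(object, ...) {
  df <- object$per_side
  df$artery <- factor(df$artery, levels = artery_order())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$artery, y = .data$mean_mm,
                                   fill = .data$side)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_mm - .data$sd_mm, 0),
                   ymax = .data$mean_mm + .data$sd_mm),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "deviation (mm)",
                  title = "Projection deviation by artery",
                  subtitle = sprintf("overall mean %.2f mm (SD %.2f mm)",
                                     object$overall$mean_mm,
                                     object$overall$sd_mm)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ar_registration <- function(object, ...) {
  lm <- tibble::tibble(u = object$landmarks2d[, 1],
                       v = object$landmarks2d[, 2])
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = lm, ggplot2::aes(x = .data$u, y = .data$v),
                        shape = 3, colour = "grey40")
  if (nrow(object$overlay) > 0) {
    p <- p + ggplot2::geom_path(
      data = object$overlay,
      ggplot2::aes(x = .data$u, y = .data$v, group = .data$curve,
                   colour = .data$label))
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u (px)", y = "v (px)", colour = "artery",
                  title = "Projected arterial overlay") +
    ggplot2::theme_minimal()
}
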
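#' Plot a granule size distribution
#'
#' Number- and volume-weighted percentages per diameter bin on a log-x
#' axis, the standard way wheat-starch A/B/C trimodality is displayed.
#'
#' @param object A [size_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gcw_size_distribution <- function(object, ...) {
  if (object$empty) stop_input("empty size distribution")
  df <- tidyr::pivot_longer(object$by_bin,
                            cols = c("number_pct", "volume_pct"),
                            names_to = "weighting", values_to = "pct")
  df$weighting <- ifelse(df$weighting == "number_pct", "number", "volume")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$pct,
                                   colour = .data$weighting)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Max-Feret diameter (µm)", y = "proportion (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one slice of a quantification
#'
#' Fused SHG slice with the envelope outline and granule label boundaries
#' overlaid.
#'
#' @param object A [quantify_stack()] result.
#' @param z Slice index; defaults to the size-distribution representative
#'   slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gcw_quantification <- function(object, z = NULL, ...) {
  if (is.null(z)) z <- object$sizes$representative_z
  if (is.na(z)) z <- object$shg_range$z_start
  sl <- object$combined[, , z]
  df <- expand.grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$intensity <- as.vector(sl)
  df$envelope <- as.vector(object$envelope$mask[, , z]) * 1
  df$granule <- as.vector(object$labels$labels[, , z] > 0) * 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$envelope),
                          breaks = 0.5, colour = "yellow",
                          linewidth = 0.3) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$granule),
                          breaks = 0.5, colour = "magenta",
                          linewidth = 0.2) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice %d: fused SHG, envelope (yellow), granules (magenta)", z),
                  x = NULL, y = NULL, fill = "SHG") +
    ggplot2::theme_minimal()
}
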
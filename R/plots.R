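#' Plot one daily path colored by behavior
#'
#' @param seg Output of [segment_behavior()].
#' @param individual,date Which individual-day to draw (defaults to the
#'   first).
#' @return A ggplot.
#' @export
plot_daily_path <- function(seg, individual = NULL, date = NULL) {
  individual <- individual %||% seg$individual_id[1]
  d <- seg[seg$individual_id == individual, ]
  date <- date %||% d$period_date[1]
  d <- dplyr::arrange(d[d$period_date == date, ], .data$timestamp)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s — %s", individual, date),
                  x = "x (m)", y = "y (m)", color = "behavior") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.syndrome_space <- function(object, ...) {
  s <- object$scores
  if (!all(c("PC1", "PC2") %in% names(s))) {
    abort("Need at least two components to plot.")
  }
  p <- ggplot2::ggplot(s, ggplot2::aes(.data$PC1, .data$PC2))
  if ("species" %in% names(s)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$species))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", object$pct_variance[1]),
    y = sprintf("PC2 (%.1f%%)", object$pct_variance[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.utilization_distribution <- function(object, p = 0.95, ...) {
  df <- expand.grid(x = object$gx, y = object$gy)
  df$z <- as.vector(object$z)
  dens <- sort(as.vector(object$z), decreasing = TRUE)
  cum <- cumsum(dens) * object$cell_area
  lev <- dens[which(cum >= p)[1]]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$z), breaks = lev,
                          color = "white") +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
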
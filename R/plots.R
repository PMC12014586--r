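#' Plot a simulation snapshot (cells over the ECM density field)
#'
#' Mirrors the standard rendering of this model family: ECM density in
#' orange (0 = white, 1 = deep orange), cells as semi-transparent green
#' disks.
#'
#' @param object A `spheroid_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spheroid_sim <- function(object, ...) {
  g <- object$grid
  cx <- g$origin[1] + (seq_len(g$nx) - 0.5) * g$voxel_size
  cy <- g$origin[2] + (seq_len(g$ny) - 0.5) * g$voxel_size
  dens <- tidyr::expand_grid(iy = seq_len(g$ny), ix = seq_len(g$nx))
  dens$x <- cx[dens$ix]
  dens$y <- cy[dens$iy]
  dens$rho <- g$density[cbind(dens$ix, dens$iy)]
  cells <- object$cells
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = dens,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$rho)) +
    ggplot2::scale_fill_gradient(name = expression(rho),
                                 low = "white", high = "darkorange",
                                 limits = c(0, 1)) +
    ggplot2::geom_point(data = cells,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$radius),
                        colour = "forestgreen", alpha = 0.5) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Growth-curve ribbon plot across replicates
#'
#' Mean with 25th--75th percentile ribbon of a metric over time, one
#' colour per condition when the input carries a `condition` column.
#'
#' @param x A `spheroid_replicates`, or a summary tibble from
#'   [aggregate_replicates()] (optionally with an extra `condition`
#'   column).
#' @param metric Metric name to plot.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(x, metric = "relative_growth") {
  smry <- if (inherits(x, "spheroid_replicates")) x$summary else x
  smry <- dplyr::filter(smry, .data$metric == !!metric)
  has_cond <- "condition" %in% names(smry)
  aes_base <- if (has_cond) {
    ggplot2::aes(x = .data$time_min / 60, y = .data$mean,
                 colour = .data$condition, fill = .data$condition)
  } else {
    ggplot2::aes(x = .data$time_min / 60, y = .data$mean)
  }
  ggplot2::ggplot(smry, aes_base) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = metric) +
    ggplot2::theme_minimal()
}

#' Box plots of a metric at selected timepoints
#'
#' @param x A `spheroid_replicates` (or its per-replicate metrics tibble).
#' @param metric Metric column to plot.
#' @param at_hours Timepoints (h) to include.
#' @return A ggplot.
#' @export
plot_metric_boxes <- function(x, metric = "cell_count",
                              at_hours = c(24, 48, 72, 96)) {
  m <- if (inherits(x, "spheroid_replicates")) x$metrics else x
  m <- dplyr::filter(m, .data$time_min %in% (at_hours * 60))
  ggplot2::ggplot(m, ggplot2::aes(x = factor(.data$time_min / 60),
                                  y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "time (h)", y = metric) +
    ggplot2::theme_minimal()
}

#' Heatmap of a sweep result
#'
#' Renders a [sweep_scenarios()] table as a heatmap over two axes, with
#' the model family's conventional colour ranges (relative growth 1-8,
#' Delaunay distance 10-30 um) for visual comparability.
#'
#' @param sweep_tbl Output of [sweep_scenarios()].
#' @param x,y Axis column names.
#' @param fill Fill column: `"mean_growth"` or `"mean_delaunay_um"`.
#' @return A ggplot.
#' @export
plot_sweep_heatmap <- function(sweep_tbl, x = "S0", y = "rdeg0",
                               fill = "mean_growth") {
  lims <- if (fill == "mean_growth") c(1, 8) else c(10, 30)
  ggplot2::ggplot(sweep_tbl,
                  ggplot2::aes(x = factor(.data[[x]]),
                               y = factor(.data[[y]]),
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = lims, oob = scales_squish) +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}

# clamp out-of-range values into the colour limits (avoids a scales dep)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
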
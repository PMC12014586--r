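#' Rasterized union-of-disks spheroid area
#'
#' The domain is divided into an `n` by `n` grid; every grid element whose
#' centre lies inside (or on the boundary of) at least one cell disk is
#' counted once, and the count is rescaled to um^2. Overlapping disks are
#' not double-counted.
#'
#' @param cells A data frame with columns `x`, `y`, `radius` (um).
#' @param domain Numeric length-2: the interval `[lo, hi]` spanned by the
#'   raster in both x and y (um).
#' @param n Grid elements per axis.
#' @return Area (um^2).
#' @examples
#' cells <- tibble::tibble(x = 0, y = 0, radius = 10)
#' raster_area(cells, c(-50, 50), 2000)  # ~ pi * 100
#' @export
raster_area <- function(cells, domain, n = 5000) {
  stopifnot(length(domain) == 2, domain[2] > domain[1], n >= 1)
  if (nrow(cells) == 0) return(0)
  raster_area_cpp(cells$x, cells$y, cells$radius,
                  domain[1], domain[2], as.integer(n))
}

#' Area growth relative to the initial time
#'
#' `g(t) = area(t) / area(0)`, so `g(0) = 1`.
#'
#' @param area Numeric vector of areas, first element at the initial time.
#' @return Dimensionless growth series.
#' @export
relative_growth <- function(area) {
  if (!length(area)) return(numeric(0))
  if (is.na(area[1]) || area[1] <= 0) {
    stop("initial area must be positive", call. = FALSE)
  }
  area / area[1]
}

#' Delaunay mean distance between cell centres
#'
#' Builds the Delaunay triangulation of the centres and returns the mean
#' Euclidean length over the unique edge set. A compactness statistic:
#' lower values mean a denser spheroid. Degenerate inputs (fewer than 3
#' distinct points, or all collinear) yield `NA`.
#'
#' @param points A data frame or matrix with columns/`x`,`y` coordinates
#'   (um).
#' @return Mean edge length (um), or `NA_real_` when undefined.
#' @examples
#' tri <- tibble::tibble(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2))
#' delaunay_mean_distance(tri)  # 1: equilateral triangle
#' @export
delaunay_mean_distance <- function(points) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2])
  pts <- unique(data.frame(x = points$x, y = points$y))
  if (nrow(pts) < 3) return(NA_real_)
  # degenerate (all collinear) input has no triangulation
  dx <- pts$x - pts$x[1]
  dy <- pts$y - pts$y[1]
  scale <- max(1, abs(dx), abs(dy))
  if (all(abs(dx * dy[2] - dy * dx[2]) < 1e-9 * scale^2)) return(NA_real_)
  tri <- tryCatch(
    suppressWarnings(deldir::deldir(pts$x, pts$y, round = FALSE)),
    error = function(e) NULL
  )
  if (is.null(tri) || nrow(tri$delsgs) == 0) return(NA_real_)
  seg <- tri$delsgs
  mean(sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2))
}

#' Aggregate replicate metric series
#'
#' Elementwise mean and 25th/75th percentiles (linear interpolation
#' between order statistics) across replicates at each timepoint, for each
#' metric. Replicates must share the same time grid.
#'
#' @param metrics Per-replicate metrics tibble with columns `replicate`,
#'   `time_min` and one column per metric.
#' @return Long tibble: `time_min`, `metric`, `mean`, `p25`, `p75`.
#' @export
aggregate_replicates <- function(metrics) {
  tms <- split(metrics$time_min, metrics$replicate)
  if (length(unique(vapply(tms, length, integer(1)))) != 1 ||
      !all(vapply(tms, function(t) all(t == tms[[1]]), logical(1)))) {
    stop("replicates have ragged or mismatched time grids", call. = FALSE)
  }
  long <- tidyr::pivot_longer(metrics,
                              cols = -c("replicate", "time_min"),
                              names_to = "metric", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$time_min, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    p25 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    p75 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
}

# metrics series from engine snapshots (pure function of the snapshots)
metrics_from_snapshots <- function(snaps, domain, raster_n, delaunay = TRUE) {
  rows <- purrr::map(snaps, function(s) {
    cells <- tibble::tibble(x = s$x, y = s$y, radius = s$r)
    tibble::tibble(
      time_min = s$time,
      cell_count = length(s$x),
      area_um2 = raster_area(cells, domain, raster_n),
      delaunay_mean_um = if (delaunay) {
        delaunay_mean_distance(cells)
      } else {
        NA_real_
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
                relative_growth = relative_growth(.data$area_um2),
                .after = "area_um2")
}
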
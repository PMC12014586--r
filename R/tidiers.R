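#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation's metric series
#'
#' @param x A `spheroid_sim`.
#' @param ... Unused.
#' @return A long tibble: `time_min`, `metric`, `value`.
#' @export
tidy.spheroid_sim <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, cols = -"time_min",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x A `spheroid_sim`.
#' @param ... Unused.
#' @return A one-row tibble: end time, final cell count, final relative
#'   growth, final Delaunay mean distance, division count and front-clamp
#'   count.
#' @export
glance.spheroid_sim <- function(x, ...) {
  m <- x$metrics
  fin <- m[m$time_min == max(m$time_min), ]
  tibble::tibble(
    t_end_min = fin$time_min,
    n_cells = fin$cell_count,
    relative_growth = fin$relative_growth,
    delaunay_mean_um = fin$delaunay_mean_um,
    n_divisions = x$counters$n_divisions,
    n_clamped_fronts = x$counters$n_clamped_fronts
  )
}

#' Tidy replicate metrics
#'
#' @param x A `spheroid_replicates`.
#' @param ... Unused.
#' @return A long tibble: `replicate`, `time_min`, `metric`, `value`.
#' @export
tidy.spheroid_replicates <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, cols = -c("replicate", "time_min"),
                      names_to = "metric", values_to = "value")
}

#' One-row-per-replicate summary
#'
#' @param x A `spheroid_replicates`.
#' @param ... Unused.
#' @return Tibble with one row per replicate at the final time.
#' @export
glance.spheroid_replicates <- function(x, ...) {
  m <- x$metrics
  fin <- m[m$time_min == max(m$time_min), ]
  tibble::as_tibble(fin)
}
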
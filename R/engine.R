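#' Calibrated hexagonal packing spacing
#'
#' The initial spheroid is a hexagonally packed disc of cells. The lattice
#' spacing is not free: it is calibrated, once per cell radius, so that a
#' disc of radius 100 um (a 200-um spheroid) holds exactly 139 cells. The
#' scan covers `[1.8 R, 2.0 R]` and the midpoint of the sub-interval that
#' attains 139 is used.
#'
#' @param cell_r Cell radius (um).
#' @param target Cell count the 100-um disc must attain.
#' @return Spacing (um).
#' @export
calibrate_hex_spacing <- function(cell_r, target = 139) {
  cand <- seq(1.8 * cell_r, 2.0 * cell_r, length.out = 801)
  counts <- vapply(cand, function(a) nrow(hex_disc_points(a, 100)), integer(1))
  hit <- cand[counts == target]
  if (!length(hit)) {
    stop("no spacing in [1.8R, 2.0R] yields ", target,
         " cells in a 100 um disc (cell radius ", signif(cell_r, 4), " um)",
         call. = FALSE)
  }
  (min(hit) + max(hit)) / 2
}

# hexagonal lattice points (origin included) whose centres lie in a disc
hex_disc_points <- function(spacing, disc_r) {
  rowh <- spacing * sqrt(3) / 2
  jmax <- ceiling(disc_r / rowh) + 1
  imax <- ceiling(disc_r / spacing) + 1
  pts <- lapply(-jmax:jmax, function(j) {
    yy <- j * rowh
    off <- if (j %% 2 == 0) 0 else spacing / 2
    xx <- (-imax:imax) * spacing + off
    keep <- xx^2 + yy^2 <= disc_r^2 + 1e-9
    cbind(x = xx[keep], y = rep(yy, sum(keep)))
  })
  as.data.frame(do.call(rbind, pts))
}

#' Initial condition: packed spheroid in a homogeneous matrix
#'
#' Cells are hexagonally packed (calibrated spacing, see
#' [calibrate_hex_spacing()]) in a disc of the requested diameter centred
#' at the origin, all at full volume with zero motility direction. The ECM
#' density is 0 at voxels whose centres lie within the disc (the spheroid
#' has displaced the matrix) and 1 elsewhere.
#'
#' @param diameter Spheroid diameter (um); defaults to
#'   `params$spheroid_diameter`.
#' @param params An `ecm_params` object.
#' @return An object of class `spheroid_state`: list with `cells` (a
#'   [cell_table()]), `grid` (an [ecm_grid()]), `params`, `clock` (min) and
#'   `meta` (the calibrated spacing).
#' @examples
#' st <- init_spheroid(200, model_params())
#' nrow(st$cells)  # 139
#' @export
init_spheroid <- function(diameter = NULL, params = model_params()) {
  if (is.null(diameter)) diameter <- params$spheroid_diameter
  if (diameter > 2 * params$domain_half_width) {
    stop("spheroid diameter exceeds the domain width", call. = FALSE)
  }
  cell_r <- cell_radius(params$cell_volume_max)
  spacing <- calibrate_hex_spacing(cell_r)
  pts <- hex_disc_points(spacing, diameter / 2)
  # deterministic order: by y then x
  pts <- pts[order(pts$y, pts$x), , drop = FALSE]
  cells <- cell_table(pts$x, pts$y, volume = params$cell_volume_max)

  grid <- ecm_grid(params$domain_half_width, params$voxel_size, density = 1)
  cx <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$voxel_size
  cy <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$voxel_size
  inside <- outer(cx^2, cy^2, "+") <= (diameter / 2)^2
  grid$density[inside] <- 0

  structure(
    list(cells = cells, grid = grid, params = params, clock = 0,
         meta = list(hex_spacing = spacing)),
    class = "spheroid_state"
  )
}

#' Run one spheroid simulation
#'
#' Advances the hybrid model from an initial packed spheroid: mechanics
#' (voxel selection, ECM degradation, direction resampling, velocities,
#' forward-Euler move) every `dt_mech`, phenotype (division, then volume
#' growth) every `dt_cell`, recording metrics every `record_every` minutes.
#' Deterministic given `(params, seed)`.
#'
#' @param params An `ecm_params` object.
#' @param t_end End time (min); must be a multiple of `record_every`.
#' @param seed Integer seed for the replicate's RNG stream, or `NULL` to
#'   use the current RNG state.
#' @param record_every Metrics cadence (min); must be a multiple of
#'   `dt_mech`.
#' @param diameter Initial spheroid diameter (um); defaults to
#'   `params$spheroid_diameter`.
#' @param delaunay Compute the Delaunay mean distance at each timepoint?
#' @param keep_snapshots Keep per-timepoint cell positions in the result?
#' @return An object of class `spheroid_sim`: list with `metrics` (tibble:
#'   `time_min`, `cell_count`, `area_um2`, `relative_growth`,
#'   `delaunay_mean_um`), final `cells` and `grid`, `params`, `seed`,
#'   event `counters`, and `meta`.
#' @examples
#' \donttest{
#' sim <- simulate_spheroid(model_params(), t_end = 120, seed = 1)
#' sim$metrics
#' }
#' @export
simulate_spheroid <- function(params = model_params(),
                              t_end = 96 * 60,
                              seed = NULL,
                              record_every = 60,
                              diameter = NULL,
                              delaunay = TRUE,
                              keep_snapshots = FALSE) {
  stopifnot(t_end >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  rec_steps <- record_every / p$dt_mech
  if (abs(rec_steps - round(rec_steps)) > 1e-8) {
    stop("`record_every` must be a multiple of `dt_mech`", call. = FALSE)
  }
  n_steps <- t_end / p$dt_mech
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("`t_end` must be a multiple of `dt_mech`", call. = FALSE)
  }
  if (t_end > 0 && (t_end / record_every) %% 1 != 0) {
    stop("`t_end` must be a multiple of `record_every`", call. = FALSE)
  }

  st <- init_spheroid(diameter, p)
  cpp_par <- list(
    ox = st$grid$origin[1], oy = st$grid$origin[2],
    voxel_size = p$voxel_size, nx = st$grid$nx, ny = st$grid$ny,
    dt_mech = p$dt_mech,
    n_steps = as.integer(round(n_steps)),
    steps_per_cell = as.integer(round(p$dt_cell / p$dt_mech)),
    record_every_steps = as.integer(round(rec_steps)),
    rdeg = degradation_rate(p$rdeg0, p$delta, p$rib),
    Srib = max_speed(p$S0, p$sigma, p$rib),
    Tper = p$Tper, rdiv = p$rdiv, Nmax = as.integer(p$Nmax),
    ccca = p$ccca, cccr = p$cccr,
    adhesion_radius_multiple = p$adhesion_radius_multiple,
    growth_rate_k = p$growth_rate_k, cell_volume_max = p$cell_volume_max,
    domain_half_width = p$domain_half_width
  )
  res <- sim_run_cpp(st$cells$x, st$cells$y, st$cells$volume,
                     st$cells$dir_x, st$cells$dir_y,
                     st$grid$density, cpp_par)

  snaps <- purrr::pmap(
    list(res$snap_time, res$snap_x, res$snap_y, res$snap_r),
    function(t, x, y, r) list(time = t, x = x, y = y, r = r)
  )
  dom <- c(-p$domain_half_width, p$domain_half_width)
  metrics <- metrics_from_snapshots(snaps, dom, p$raster_n, delaunay)

  cells <- tibble::as_tibble(res$cells)
  grid <- st$grid
  grid$density <- res$rho

  structure(
    list(metrics = metrics, cells = cells, grid = grid, params = p,
         seed = seed,
         counters = list(n_divisions = res$n_divisions,
                         n_clamped_fronts = res$n_clamped_fronts,
                         n_coincident = res$n_coincident),
         snapshots = if (keep_snapshots) snaps else NULL,
         meta = st$meta),
    class = "spheroid_sim"
  )
}

#' @export
print.spheroid_sim <- function(x, ...) {
  tmax <- max(x$metrics$time_min)
  cat(sprintf(
    "<spheroid_sim> %d cells after %g h (%g divisions), relative growth %.3g\n",
    nrow(x$cells), tmax / 60, x$counters$n_divisions,
    x$metrics$relative_growth[x$metrics$time_min == tmax]))
  invisible(x)
}

#' Run replicate simulations
#'
#' Replicate `k` runs with seed `base_seed + k`; replicates are otherwise
#' identical.
#'
#' @inheritParams simulate_spheroid
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Base seed; replicate `k` uses `base_seed + k`.
#' @param keep_runs Keep the individual `spheroid_sim` objects (with final
#'   states) in the result?
#' @return An object of class `spheroid_replicates`: list with `metrics`
#'   (per-replicate tibble, column `replicate`), `summary`
#'   (mean/p25/p75 per timepoint from [aggregate_replicates()]), `params`,
#'   and optionally `runs`.
#' @export
run_replicates <- function(params = model_params(),
                           n_reps = 10,
                           base_seed = 0,
                           t_end = 96 * 60,
                           record_every = 60,
                           diameter = NULL,
                           delaunay = TRUE,
                           keep_runs = FALSE) {
  stopifnot(n_reps >= 1)
  runs <- purrr::map(seq_len(n_reps), function(k) {
    simulate_spheroid(params, t_end = t_end, seed = base_seed + k,
                      record_every = record_every, diameter = diameter,
                      delaunay = delaunay)
  })
  metrics <- purrr::imap(runs, function(r, k) {
    dplyr::mutate(r$metrics, replicate = k, .before = 1)
  })
  metrics <- dplyr::bind_rows(metrics)
  structure(
    list(metrics = metrics,
         summary = aggregate_replicates(metrics),
         params = params,
         runs = if (keep_runs) runs else NULL),
    class = "spheroid_replicates"
  )
}

#' @export
print.spheroid_replicates <- function(x, ...) {
  nr <- length(unique(x$metrics$replicate))
  tmax <- max(x$metrics$time_min)
  fin <- dplyr::filter(x$summary, .data$time_min == tmax,
                       .data$metric == "relative_growth")
  cat(sprintf(
    "<spheroid_replicates> %d replicates to %g h; mean relative growth %.3g [p25 %.3g, p75 %.3g]\n",
    nr, tmax / 60, fin$mean, fin$p25, fin$p75))
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Writes the per-snapshot cell table (CSV), the final ECM density matrix
#' (plain text + JSON sidecar), the tidy metrics CSV and a JSON run
#' manifest with the fully resolved configuration.
#'
#' @param sim A `spheroid_sim`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  cells <- dplyr::transmute(
    sim$cells,
    id = .data$id, x_um = .data$x, y_um = .data$y,
    radius_um = .data$radius, volume_um3 = .data$volume,
    dir_x = .data$dir_x, dir_y = .data$dir_y, speed_um_min = .data$speed)
  utils::write.csv(cells, file.path(dir, "cells_final.csv"),
                   row.names = FALSE)
  write_ecm_grid(sim$grid, file.path(dir, "ecm_final.txt"))
  manifest <- list(
    params = unclass(sim$params), seed = sim$seed,
    counters = sim$counters, meta = sim$meta,
    package_version = as.character(utils::packageVersion("spheroidECM")))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
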
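#' Scenario presets
#'
#' Fully resolved parameter sets for the three study conditions:
#'
#' * `"noninvasive"` — weak cell-ECM interactions (MCF7-like):
#'   `rdeg0 = 0.0001` min^-1, `S0 = 0.1` um/min.
#' * `"invasive"` — strong cell-ECM interactions (HCC1954-like):
#'   `rdeg0 = 0.0032` min^-1, `S0 = 0.7` um/min.
#' * `"gm6001"` — the invasive cell line under pan-MMP inhibition, which
#'   blocks enzymatic ECM degradation but not mechanical remodelling:
#'   invasive parameters with `rdeg0 = 0.0004` min^-1. Compared at 72 h.
#'
#' All presets share `delta = 0.02` mM^-1, `sigma = 0.035` mM^-1,
#' `rdiv = 0.00072` min^-1, a 200-um spheroid, 10 replicates, and 96 h
#' horizon (72 h for `"gm6001"`).
#'
#' @param name One of `"noninvasive"`, `"invasive"`, `"gm6001"`.
#' @param rib Ribose concentration (mM).
#' @param ... Overrides passed on to [model_params()].
#' @return An object of class `spheroid_scenario`: list with `name`,
#'   `params` (an `ecm_params`), `t_end` (min), `ribose_levels` (mM) and
#'   `n_reps`.
#' @examples
#' preset("invasive")$params$rdeg0   # 0.0032
#' preset("gm6001")$params$rdeg0    # 4e-04
#' @export
preset <- function(name, rib = 0, ...) {
  presets <- list(
    noninvasive = list(rdeg0 = 0.0001, S0 = 0.1, t_end = 96 * 60),
    invasive    = list(rdeg0 = 0.0032, S0 = 0.7, t_end = 96 * 60),
    gm6001      = list(rdeg0 = 0.0004, S0 = 0.7, t_end = 72 * 60)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset `", name, "`; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  pr <- presets[[name]]
  params <- model_params(rdeg0 = pr$rdeg0, S0 = pr$S0,
                         delta = 0.02, sigma = 0.035,
                         rdiv = 0.00072, rib = rib,
                         spheroid_diameter = 200, ...)
  structure(
    list(name = name, params = params, t_end = pr$t_end,
         ribose_levels = c(0, 50, 200), n_reps = 10),
    class = "spheroid_scenario"
  )
}

#' @export
print.spheroid_scenario <- function(x, ...) {
  cat(sprintf(
    "<spheroid_scenario> %s: rdeg0 = %g min^-1, S0 = %g um/min, t_end = %g h\n",
    x$name, x$params$rdeg0, x$params$S0, x$t_end / 60))
  invisible(x)
}

#' Run a scenario preset
#'
#' Runs replicate simulations for a preset (or a custom `ecm_params`) at a
#' given ribose concentration.
#'
#' @param scenario A preset name, a `spheroid_scenario`, or an
#'   `ecm_params` object.
#' @param rib Ribose concentration (mM).
#' @param n_reps Replicates (defaults to the scenario's count).
#' @param base_seed Base seed; replicate `k` uses `base_seed + k`.
#' @param t_end End time (min); defaults to the scenario's horizon.
#' @param ... Passed to [run_replicates()].
#' @return A `spheroid_replicates` object.
#' @export
run_scenario <- function(scenario, rib = 0, n_reps = NULL, base_seed = 0,
                         t_end = NULL, ...) {
  if (is.character(scenario)) scenario <- preset(scenario, rib = rib)
  if (inherits(scenario, "spheroid_scenario")) {
    params <- scenario$params
    params$rib <- rib
    params <- validate_params(params)
    if (is.null(n_reps)) n_reps <- scenario$n_reps
    if (is.null(t_end)) t_end <- scenario$t_end
  } else if (inherits(scenario, "ecm_params")) {
    params <- scenario
    params$rib <- rib
    params <- validate_params(params)
    if (is.null(n_reps)) n_reps <- 10
    if (is.null(t_end)) t_end <- 96 * 60
  } else {
    stop("`scenario` must be a preset name, spheroid_scenario or ecm_params",
         call. = FALSE)
  }
  run_replicates(params, n_reps = n_reps, base_seed = base_seed,
                 t_end = t_end, ...)
}

#' Parameter sweep over cell-ECM interaction parameters
#'
#' Runs replicate batches over a full factorial grid and reports, per grid
#' point, the mean relative area growth and mean Delaunay distance at the
#' final time. Two families of axes are supported, mirroring the model's
#' two analyses: `rdiv` x `S0` x `rdeg0` (interaction-parameter sweep at
#' fixed ribose) and `delta` x `sigma` x `rib` (ribose-sensitivity sweep).
#' Any subset of axes may be length 1.
#'
#' @param params Baseline `ecm_params`; swept fields are overridden.
#' @param grid Named list of numeric axes; names must be `model_params()`
#'   argument names (e.g. `list(rdiv = c(4e-4, 6e-4, 8e-4), S0 = ...,
#'   rdeg0 = ...)`).
#' @param n_reps Replicates per grid point.
#' @param base_seed Base seed (each grid point uses the same replicate
#'   seeds, so points differ only through their parameters).
#' @param t_end End time (min).
#' @param ... Passed to [run_replicates()].
#' @return Tidy tibble: one row per grid point with the axis values,
#'   `mean_growth` and `mean_delaunay_um` at `t_end`.
#' @export
sweep_scenarios <- function(params = model_params(),
                            grid = list(rdiv = c(0.0004, 0.0006, 0.0008),
                                        S0 = seq(0.1, 0.8, by = 0.1),
                                        rdeg0 = 0.0001 * 2^(0:7)),
                            n_reps = 10, base_seed = 0, t_end = 96 * 60,
                            ...) {
  known <- names(formals(model_params))
  bad <- setdiff(names(grid), known)
  if (length(bad)) {
    stop("unknown sweep axis: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pts <- do.call(tidyr::expand_grid, grid)
  extra <- list(...)
  res <- purrr::pmap(pts, function(...) {
    ov <- list(...)
    p <- params
    p[names(ov)] <- ov
    p <- validate_params(p)
    reps <- do.call(run_replicates,
                    c(list(p, n_reps = n_reps, base_seed = base_seed,
                           t_end = t_end), extra))
    fin <- dplyr::filter(reps$summary, .data$time_min == t_end)
    tibble::tibble(
      mean_growth = fin$mean[fin$metric == "relative_growth"],
      mean_delaunay_um = fin$mean[fin$metric == "delaunay_mean_um"]
    )
  })
  dplyr::bind_cols(pts, dplyr::bind_rows(res))
}
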
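#' Model parameters for a spheroid/ECM simulation
#'
#' Constructs and validates the full parameter set of the hybrid model:
#' agent mechanics, ECM degradation, ribose scaling laws, proliferation,
#' time stepping, domain geometry and measurement resolution.
#'
#' The two ribose scaling laws are
#' \deqn{r_{deg,rib} = r_{deg,0}\, e^{-\delta\, rib}, \qquad
#'       S_{rib} = S_0\, e^{-\sigma\, rib},}
#' so at `rib = 0` (no collagen cross-linking) the base rate/speed apply, and
#' increasing ribose attenuates both exponentially.
#'
#' @param rdeg0 Base ECM degradation rate at 0 mM ribose (min^-1).
#' @param delta Ribose sensitivity of the degradation rate (mM^-1).
#' @param S0 Maximum cell-ECM interaction speed at 0 mM ribose (um/min).
#' @param sigma Ribose sensitivity of the maximum speed (mM^-1).
#' @param rib Ribose concentration (mM).
#' @param rdiv Proliferation rate (min^-1). Default 0.00072 min^-1, the live
#'   cell-cycle rate of MCF10A breast epithelial cells.
#' @param Nmax Overcrowding threshold (neighbour count at or above which
#'   proliferation stops). Default 6: a cell fully surrounded by neighbours
#'   under hexagonal packing in the monolayer plane.
#' @param Tper Persistence time of the motility direction (min). The
#'   direction is resampled each mechanics step with probability
#'   `dt_mech / Tper`. Use `Inf` for a never-changing direction.
#' @param dt_mech Mechanics time step (min); movement and ECM remodelling.
#' @param dt_cell Phenotype time step (min); division and volume growth.
#'   Must be an integer multiple of `dt_mech`.
#' @param cell_volume_max Target (maximum) cell volume (um^3); the default
#'   2494 um^3 gives a cell radius of about 8.41 um.
#' @param adhesion_radius_multiple Interaction (adhesion) radius as a
#'   multiple of the cell radius.
#' @param ccca Cell-cell adhesion strength (um/min).
#' @param cccr Cell-cell repulsion strength (um/min).
#' @param growth_rate_k Relaxation rate of cell volume toward its target
#'   (min^-1); the volume deficit halves every `log(2)/growth_rate_k` min.
#' @param voxel_size ECM voxel edge length (um).
#' @param domain_half_width Half-width of the square simulation domain (um).
#' @param spheroid_diameter Initial spheroid diameter (um).
#' @param raster_n Rasterization grid size per axis for the area measurement.
#'
#' @return An object of class `ecm_params`: a validated named list.
#' @examples
#' p <- model_params()
#' p$rdeg0
#' degradation_rate(0.0032, 0.02, 50)
#' @export
model_params <- function(rdeg0 = 0.0032,
                         delta = 0.02,
                         S0 = 0.7,
                         sigma = 0.035,
                         rib = 0,
                         rdiv = 0.00072,
                         Nmax = 6,
                         Tper = 10,
                         dt_mech = 0.1,
                         dt_cell = 6,
                         cell_volume_max = 2494,
                         adhesion_radius_multiple = 1.25,
                         ccca = 0.4,
                         cccr = 10,
                         growth_rate_k = 0.01,
                         voxel_size = 20,
                         domain_half_width = 500,
                         spheroid_diameter = 200,
                         raster_n = 5000) {
  p <- list(
    rdeg0 = rdeg0, delta = delta, S0 = S0, sigma = sigma, rib = rib,
    rdiv = rdiv, Nmax = Nmax, Tper = Tper,
    dt_mech = dt_mech, dt_cell = dt_cell,
    cell_volume_max = cell_volume_max,
    adhesion_radius_multiple = adhesion_radius_multiple,
    ccca = ccca, cccr = cccr, growth_rate_k = growth_rate_k,
    voxel_size = voxel_size, domain_half_width = domain_half_width,
    spheroid_diameter = spheroid_diameter, raster_n = raster_n
  )
  validate_params(p)
}

validate_params <- function(p) {
  num1 <- function(name, allow_inf = FALSE) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter `", name, "` must be a single number", call. = FALSE)
    }
    if (!allow_inf && !is.finite(v)) {
      stop("parameter `", name, "` must be finite", call. = FALSE)
    }
    if (v < 0) stop("parameter `", name, "` must be >= 0", call. = FALSE)
    v
  }
  for (nm in c("rdeg0", "delta", "S0", "sigma", "rib", "rdiv",
               "dt_mech", "dt_cell", "cell_volume_max",
               "adhesion_radius_multiple", "ccca", "cccr",
               "growth_rate_k", "voxel_size", "domain_half_width",
               "spheroid_diameter")) {
    num1(nm)
  }
  num1("Tper", allow_inf = TRUE)
  if (p$dt_mech <= 0) stop("`dt_mech` must be > 0", call. = FALSE)
  if (p$dt_mech > p$dt_cell) {
    stop("`dt_mech` must not exceed `dt_cell`", call. = FALSE)
  }
  ratio <- p$dt_cell / p$dt_mech
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("`dt_cell` must be an integer multiple of `dt_mech`", call. = FALSE)
  }
  if (p$Nmax < 1 || p$Nmax != round(p$Nmax)) {
    stop("`Nmax` must be an integer >= 1", call. = FALSE)
  }
  if (p$raster_n < 1 || p$raster_n != round(p$raster_n)) {
    stop("`raster_n` must be an integer >= 1", call. = FALSE)
  }
  if (p$Tper < p$dt_mech) {
    stop("`Tper` must be >= `dt_mech` (resampling probability would exceed 1)",
         call. = FALSE)
  }
  if (p$cell_volume_max <= 0) stop("`cell_volume_max` must be > 0", call. = FALSE)
  if (p$voxel_size <= 0) stop("`voxel_size` must be > 0", call. = FALSE)
  if (p$domain_half_width <= 0) stop("`domain_half_width` must be > 0", call. = FALSE)
  structure(p, class = "ecm_params")
}

#' @export
print.ecm_params <- function(x, ...) {
  cat("<ecm_params>\n")
  cat(sprintf("  ribose %g mM: rdeg = %.3g min^-1, S = %.3g um/min\n",
              x$rib,
              degradation_rate(x$rdeg0, x$delta, x$rib),
              max_speed(x$S0, x$sigma, x$rib)))
  df <- data.frame(value = unlist(x))
  print(df, ...)
  invisible(x)
}

#' Ribose-dependent ECM degradation rate
#'
#' Exponential attenuation of the base degradation rate by ribose-induced
#' collagen cross-linking: `rdeg0 * exp(-delta * rib)`.
#'
#' @param rdeg0 Base degradation rate at 0 mM ribose (min^-1).
#' @param delta Ribose sensitivity (mM^-1); `delta = 0` removes the ribose
#'   effect entirely.
#' @param rib Ribose concentration (mM).
#' @return Degradation rate (min^-1).
#' @examples
#' degradation_rate(0.0032, 0.02, 50)   # ~0.001
#' degradation_rate(0.0032, 0.02, 200)  # ~6e-5
#' @export
degradation_rate <- function(rdeg0, delta, rib) {
  check_nonneg(rdeg0 = rdeg0, delta = delta, rib = rib)
  rdeg0 * exp(-delta * rib)
}

#' Ribose-dependent maximum cell-ECM interaction speed
#'
#' Exponential attenuation of the maximum cell-ECM speed by ribose-induced
#' collagen cross-linking: `S0 * exp(-sigma * rib)`.
#'
#' @param S0 Maximum cell-ECM interaction speed at 0 mM ribose (um/min).
#' @param sigma Ribose sensitivity (mM^-1); `sigma = 0` removes the ribose
#'   effect entirely.
#' @param rib Ribose concentration (mM).
#' @return Maximum speed (um/min).
#' @examples
#' max_speed(0.7, 0.035, 50)   # ~0.1
#' max_speed(0.7, 0.035, 200)  # ~6e-4
#' @export
max_speed <- function(S0, sigma, rib) {
  check_nonneg(S0 = S0, sigma = sigma, rib = rib)
  S0 * exp(-sigma * rib)
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop("`", nm, "` must be numeric and >= 0", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a flat key/value parameter configuration
#'
#' Reads a YAML (or JSON, which is a YAML subset) file of flat
#' `key: value` pairs whose keys are the `model_params()` argument names.
#' Unknown keys are rejected to catch typos.
#'
#' @param path Path to the configuration file.
#' @param overrides Optional named list applied on top of the file, e.g.
#'   parsed from command-line `--param key=value` flags.
#' @return A validated `ecm_params` object.
#' @export
read_params_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a mapping of key: value pairs")
  cfg[names(overrides)] <- overrides
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "\nknown keys: ", paste(known, collapse = ", "), call. = FALSE)
  }
  do.call(model_params, cfg)
}

#' Cell radius corresponding to a volume
#'
#' Radius of a sphere of volume `V`: `(3 V / 4 pi)^(1/3)`.
#'
#' @param V Volume (um^3).
#' @return Radius (um).
#' @export
cell_radius <- function(V) (3 * V / (4 * pi))^(1 / 3)
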
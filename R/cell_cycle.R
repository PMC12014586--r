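#' Inhibition-of-proliferation factor
#'
#' Crowding- and matrix-gated proliferation: a cell with `Ni >= Nmax`
#' neighbours is fully inhibited (factor 0); otherwise the factor is
#' `1 - rho`, with `rho` the ECM density of the voxel nearest the cell
#' *position* (dense matrix compresses the spheroid and slows division).
#' An isolated cell (`Ni = 0`) is treated like the uncrowded branch:
#' penalising isolation would contradict the crowding rationale.
#'
#' @param Ni Neighbour count (>= 0, vectorised).
#' @param rho ECM density in \[0, 1\] at the cell position.
#' @param Nmax Overcrowding threshold.
#' @return Factor in \[0, 1\].
#' @export
inhibition_factor <- function(Ni, rho, Nmax = 6) {
  check_rho(rho)
  if (any(Ni < 0)) stop("`Ni` must be >= 0", call. = FALSE)
  ifelse(Ni >= Nmax, 0, 1 - rho)
}

#' Stochastic division attempt
#'
#' A cell divides during a phenotype step of length `dt` with probability
#' `rdiv * inhibition_factor(Ni, rho, Nmax) * dt`. On division the parent
#' volume is halved, both daughters inherit the parent's state, and they
#' are placed side by side at `x_parent +/- (R_parent / 2) * u` for a
#' uniform random in-plane unit vector `u`, so both centres lie inside the
#' original cell.
#'
#' @param cell One-row cell table (the parent).
#' @param Ni Parent's neighbour count.
#' @param rho ECM density at the parent's position voxel.
#' @param rdiv Proliferation rate (min^-1).
#' @param dt Phenotype time step (min); `rdiv * dt` must not exceed 1.
#' @param Nmax Overcrowding threshold.
#' @return `NULL` when no division occurs; otherwise a two-row cell table
#'   of the daughters (ids 0; the caller assigns fresh ids).
#' @export
attempt_division <- function(cell, Ni, rho, rdiv, dt, Nmax = 6) {
  if (rdiv * dt > 1) {
    stop("`rdiv * dt` exceeds 1: division probability ill-defined",
         call. = FALSE)
  }
  f <- inhibition_factor(Ni, rho, Nmax)
  if (stats::runif(1) >= rdiv * f * dt) return(NULL)
  divide_cell(cell, stats::runif(1) * 2 * pi)
}

# deterministic split given the placement angle
divide_cell <- function(cell, angle) {
  off <- cell$radius / 2
  u <- c(cos(angle), sin(angle))
  d <- cell[c(1, 1), ]
  d$volume <- cell$volume / 2
  d$radius <- cell_radius(d$volume)
  d$x <- cell$x + c(off * u[1], -off * u[1])
  d$y <- cell$y + c(off * u[2], -off * u[2])
  d$id <- c(0L, 0L)
  d
}

#' Relax a cell volume toward its target
#'
#' After division a daughter grows back toward the target volume
#' `V_target` (the maximum cell volume) by exponential relaxation:
#' `V <- V_target - (V_target - V) * exp(-k * dt)`. Monotone, with the
#' volume deficit halving every `log(2)/k` minutes; the radius is
#' recomputed from the volume.
#'
#' @param volume Current volumes (um^3, vectorised).
#' @param V_target Target volume (um^3).
#' @param k Relaxation rate (min^-1), `>= 0`.
#' @param dt Time step (min).
#' @return Updated volumes.
#' @export
grow_volume <- function(volume, V_target, k, dt) {
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  V_target - (V_target - volume) * exp(-k * dt)
}
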
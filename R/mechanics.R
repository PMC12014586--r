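#' Cell table constructor
#'
#' Cells are rows of a tibble: `id`, position (`x`, `y`, um), `volume`
#' (um^3), `radius` (um, derived from volume), motility direction
#' (`dir_x`, `dir_y`; a unit vector or zero), and `speed` (um/min, the
#' current cell-ECM interaction speed, informational). Motion is confined
#' to the xy-plane (pseudo-2D): there is no z coordinate.
#'
#' @param x,y Positions (um).
#' @param volume Cell volumes (um^3).
#' @param dir_x,dir_y Motility direction components.
#' @return A tibble of cells.
#' @export
cell_table <- function(x, y, volume, dir_x = 0, dir_y = 0) {
  tibble::tibble(
    id = seq_along(x),
    x = as.numeric(x), y = as.numeric(y),
    volume = as.numeric(volume),
    radius = cell_radius(volume),
    dir_x = rep_len(as.numeric(dir_x), length(x)),
    dir_y = rep_len(as.numeric(dir_y), length(x)),
    speed = 0
  )
}

#' Neighbouring cells within interaction distance
#'
#' Cell j is a neighbour of cell i when `|x_j - x_i| < R_iA + R_jA`, where
#' `R_A = adhesion_radius_multiple * R` is the interaction (adhesion)
#' radius. The relation is symmetric.
#'
#' @param cells A cell table ([cell_table()]).
#' @param id Id of the focal cell.
#' @param adhesion_radius_multiple Interaction radius / cell radius.
#' @return The rows of `cells` that neighbour cell `id`.
#' @export
neighbours <- function(cells, id, adhesion_radius_multiple = 1.25) {
  i <- match(id, cells$id)
  if (is.na(i)) stop("no cell with id ", id, call. = FALSE)
  ra <- adhesion_radius_multiple * cells$radius
  d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
  keep <- d < ra + ra[i] & cells$id != id
  cells[keep, , drop = FALSE]
}

#' Neighbour count of every cell
#'
#' @inheritParams neighbours
#' @return Integer vector, one count per row of `cells`.
#' @export
neighbour_counts <- function(cells, adhesion_radius_multiple = 1.25) {
  n <- nrow(cells)
  ra <- adhesion_radius_multiple * cells$radius
  dx <- outer(cells$x, cells$x, "-")
  dy <- outer(cells$y, cells$y, "-")
  dmat <- sqrt(dx^2 + dy^2)
  lim <- outer(ra, ra, "+")
  cnt <- rowSums(dmat < lim) - 1L
  as.integer(cnt)
}

#' Cell-cell interaction velocities (adhesion + repulsion)
#'
#' Standard centre-based pair potentials: for a pair at distance
#' `d = |x_j - x_i|` with unit vector `u` pointing from j to i, cell i
#' receives an adhesion contribution `-ccca * (1 - d/(R_iA + R_jA))^2 * u`
#' when `d < R_iA + R_jA`, and a repulsion contribution
#' `+cccr * (1 - d/(R_i + R_j))^2 * u` when `d < R_i + R_j`. Contributions
#' are antisymmetric within each pair. Coincident centres are pushed apart
#' along the x-axis (fixed fallback) and counted.
#'
#' @param cells A cell table.
#' @param ccca Cell-cell adhesion strength (um/min).
#' @param cccr Cell-cell repulsion strength (um/min).
#' @param adhesion_radius_multiple Interaction radius / cell radius.
#' @return A tibble with columns `vx`, `vy` (um/min), one row per cell,
#'   plus an attribute `n_coincident` counting zero-distance pairs.
#' @export
cell_cell_velocity <- function(cells, ccca = 0.4, cccr = 10,
                               adhesion_radius_multiple = 1.25) {
  n <- nrow(cells)
  vx <- numeric(n); vy <- numeric(n)
  ra <- adhesion_radius_multiple * cells$radius
  n_coincident <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        dxv <- cells$x[i] - cells$x[j]
        dyv <- cells$y[i] - cells$y[j]
        d <- sqrt(dxv^2 + dyv^2)
        lim_a <- ra[i] + ra[j]
        lim_r <- cells$radius[i] + cells$radius[j]
        if (d >= lim_a) next
        if (d == 0) {
          ux <- 1; uy <- 0
          n_coincident <- n_coincident + 1L
        } else {
          ux <- dxv / d; uy <- dyv / d
        }
        f <- -ccca * (1 - d / lim_a)^2
        if (d < lim_r) f <- f + cccr * (1 - d / lim_r)^2
        vx[i] <- vx[i] + f * ux; vy[i] <- vy[i] + f * uy
        vx[j] <- vx[j] - f * ux; vy[j] <- vy[j] - f * uy
      }
    }
  }
  out <- tibble::tibble(vx = vx, vy = vy)
  attr(out, "n_coincident") <- n_coincident
  out
}

#' Cell-ECM adhesion velocity
#'
#' The adhesion speed grows linearly with the local ECM density (more
#' density, more adhesion sites): `v_cma = 4 * Srib * rho * d_cm`, where
#' `d_cm` is the cell's persistent random direction. The factor 4 makes the
#' *total* cell-ECM speed peak at exactly `Srib` (see
#' [total_cell_ecm_speed()]).
#'
#' @param dir_x,dir_y Motility direction (unit vector or zero).
#' @param rho Local ECM density in \[0, 1\] (front voxel of the cell).
#' @param Srib Maximum cell-ECM interaction speed (um/min).
#' @return A tibble with `vx`, `vy` (um/min).
#' @export
cell_ecm_adhesion_velocity <- function(dir_x, dir_y, rho, Srib) {
  check_rho(rho)
  s <- 4 * Srib * rho
  tibble::tibble(vx = s * dir_x, vy = s * dir_y)
}

#' Cell-ECM repulsion velocity
#'
#' Dense matrix acts as an obstacle: the repulsion cancels a fraction `rho`
#' of the driving velocity, `v_cmr = -(v_cc + v_cma) * rho`, so the total
#' velocity is `(v_cc + v_cma) * (1 - rho)`. At `rho = 1` the ECM is a
#' wall; at `rho = 0` there is no repulsion.
#'
#' @param vx,vy Components of `v_cc + v_cma` (um/min).
#' @param rho Local ECM density in \[0, 1\].
#' @return A tibble with `vx`, `vy` (um/min).
#' @export
cell_ecm_repulsion_velocity <- function(vx, vy, rho) {
  check_rho(rho)
  tibble::tibble(vx = -vx * rho, vy = -vy * rho)
}

#' Total cell-ECM interaction speed of an isolated cell
#'
#' With no neighbours the total speed is `4 * Srib * rho * (1 - rho)`:
#' zero in empty matrix (nothing to pull on) and in full matrix (wall),
#' maximal at `rho = 0.5` where it equals `Srib`.
#'
#' @param rho ECM density in \[0, 1\] (vectorised).
#' @param Srib Maximum cell-ECM interaction speed (um/min).
#' @return Speed (um/min).
#' @export
total_cell_ecm_speed <- function(rho, Srib) {
  check_rho(rho)
  4 * Srib * rho * (1 - rho)
}

check_rho <- function(rho) {
  if (anyNA(rho) || any(rho < 0 | rho > 1)) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Persistence-driven direction resampling
#'
#' Each mechanics step a cell keeps its motility direction with probability
#' `1 - dt/Tper` and otherwise resamples it as a uniform random in-plane
#' unit vector, so directions persist for `Tper` minutes on average. One
#' uniform draw per cell (plus one for the angle when resampling),
#' consumed in row order.
#'
#' @param cells A cell table.
#' @param Tper Persistence time (min); may be `Inf`.
#' @param dt Mechanics time step (min); must satisfy `dt <= Tper`.
#' @return The cell table with updated `dir_x`, `dir_y`.
#' @export
direction_update <- function(cells, Tper, dt) {
  if (dt > Tper) {
    stop("`dt` must be <= `Tper` (resampling probability would exceed 1)",
         call. = FALSE)
  }
  p <- dt / Tper
  if (p == 0) return(cells)
  for (i in seq_len(nrow(cells))) {
    if (stats::runif(1) < p) {
      ang <- stats::runif(1) * 2 * pi
      cells$dir_x[i] <- cos(ang)
      cells$dir_y[i] <- sin(ang)
    }
  }
  cells
}

#' Advance cell positions by one mechanics step
#'
#' Forward Euler: `x <- x + v * dt`. Positions must stay inside the square
#' domain `[-hw, hw]^2`; a cell leaving it aborts the step (the domain is
#' too small for the scenario).
#'
#' @param cells A cell table.
#' @param vx,vy Total velocities (um/min).
#' @param dt Time step (min).
#' @param domain_half_width Domain half-width (um), or `NULL` to skip the
#'   containment check.
#' @return The cell table with updated positions.
#' @export
step_positions <- function(cells, vx, vy, dt, domain_half_width = NULL) {
  cells$x <- cells$x + vx * dt
  cells$y <- cells$y + vy * dt
  if (!is.null(domain_half_width)) {
    hw <- domain_half_width
    if (any(abs(cells$x) > hw | abs(cells$y) > hw)) {
      stop("cell left the simulation domain; increase `domain_half_width`",
           call. = FALSE)
    }
  }
  cells
}

#' One reference mechanics step (pure R)
#'
#' The documented step order, applied synchronously from pre-step
#' positions: (1) each cell selects its interaction voxel (front voxel when
#' moving); (2) each selected voxel is degraded once per selecting cell, in
#' cell order (the exponential updates commute); (3) persistence-driven
#' direction resampling; (4) velocities `v = (v_cc + v_cma) * (1 - rho)`
#' with `rho` from the selected voxel; (5) forward-Euler move.
#'
#' This is the plain-R reference used to validate the compiled engine; it
#' is exact but O(n^2) and not meant for production runs.
#'
#' @param cells A cell table.
#' @param grid An `ecm_grid`.
#' @param params An `ecm_params` object.
#' @return `list(cells, grid)` after one `dt_mech` step.
#' @export
mechanics_step <- function(cells, grid, params) {
  p <- params
  rdeg <- degradation_rate(p$rdeg0, p$delta, p$rib)
  Srib <- max_speed(p$S0, p$sigma, p$rib)
  n <- nrow(cells)

  sel <- integer(n)
  for (i in seq_len(n)) {
    sel[i] <- select_interaction_voxel(cells[i, ], grid)
  }
  for (i in seq_len(n)) {
    grid <- degrade(grid, sel[i], rdeg, p$dt_mech)
  }
  cells <- direction_update(cells, p$Tper, p$dt_mech)

  vcc <- cell_cell_velocity(cells, p$ccca, p$cccr, p$adhesion_radius_multiple)
  rho <- grid$density[sel]
  vcma <- cell_ecm_adhesion_velocity(cells$dir_x, cells$dir_y, rho, Srib)
  vx <- (vcc$vx + vcma$vx) * (1 - rho)
  vy <- (vcc$vy + vcma$vy) * (1 - rho)
  cells$speed <- sqrt(vx^2 + vy^2)
  cells <- step_positions(cells, vx, vy, p$dt_mech, p$domain_half_width)
  list(cells = cells, grid = grid)
}
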
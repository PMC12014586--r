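#' Single-layer ECM density lattice
#'
#' A square lattice of voxels, one layer thick, each storing a local ECM
#' density `rho` in \[0, 1\]. Cells sense and degrade the density of one
#' selected voxel (nearest to their position, or to their front when
#' moving).
#'
#' @param domain_half_width Half-width of the square domain (um); the
#'   lattice spans `[-hw, hw]` in x and y.
#' @param voxel_size Voxel edge length (um). The voxel count per axis is
#'   `ceiling(2 * hw / voxel_size)`.
#' @param density Optional initial density: a single value recycled to all
#'   voxels, or an `nx` by `ny` matrix.
#' @return An object of class `ecm_grid`: a list with `origin` (corner
#'   coordinates, um), `voxel_size`, `nx`, `ny` and the `density` matrix
#'   (`density[ix, iy]`, x-index fastest).
#' @examples
#' g <- ecm_grid(domain_half_width = 100, voxel_size = 20, density = 1)
#' voxel_of_point(g, c(0, 0))
#' @export
ecm_grid <- function(domain_half_width = 500, voxel_size = 20, density = 1) {
  nx <- as.integer(ceiling(2 * domain_half_width / voxel_size))
  ny <- nx
  origin <- c(-domain_half_width, -domain_half_width)
  if (is.matrix(density)) {
    if (!all(dim(density) == c(nx, ny))) {
      stop("density matrix must be ", nx, " x ", ny, call. = FALSE)
    }
    dens <- density
  } else {
    dens <- matrix(as.numeric(density), nx, ny)
  }
  g <- structure(
    list(origin = origin, voxel_size = voxel_size, nx = nx, ny = ny,
         density = dens),
    class = "ecm_grid"
  )
  check_grid(g)
  g
}

check_grid <- function(g) {
  if (any(g$density < 0 | g$density > 1)) {
    stop("ECM density must lie in [0, 1]", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.ecm_grid <- function(x, ...) {
  cat(sprintf("<ecm_grid> %d x %d voxels of %g um, origin (%g, %g)\n",
              x$nx, x$ny, x$voxel_size, x$origin[1], x$origin[2]))
  cat(sprintf("  density range [%.4g, %.4g]\n",
              min(x$density), max(x$density)))
  invisible(x)
}

# nearest-centre axis index (0-based); ties go to the smaller index so that
# linear (row-major) indices break ties low and runs are bit-reproducible
axis_index <- function(coord, orig, h, n) {
  u <- (coord - orig) / h
  i <- floor(u)
  tie <- (u == i) & (i > 0)
  i[tie] <- i[tie] - 1
  pmin(pmax(i, 0), n - 1)
}

#' Voxel nearest to a point
#'
#' Returns the (1-based, row-major) linear index of the voxel whose centre
#' is nearest to `point`. A point equidistant between two voxel centres is
#' assigned the smaller linear index.
#'
#' @param grid An `ecm_grid`.
#' @param point Numeric length-2 `(x, y)` in um.
#' @return Integer linear index into `grid$density` (x-index fastest).
#' @export
voxel_of_point <- function(grid, point) {
  lo <- grid$origin
  hi <- grid$origin + c(grid$nx, grid$ny) * grid$voxel_size
  if (point[1] < lo[1] || point[1] > hi[1] ||
      point[2] < lo[2] || point[2] > hi[2]) {
    stop("point (", point[1], ", ", point[2], ") lies outside the domain",
         call. = FALSE)
  }
  ix <- axis_index(point[1], lo[1], grid$voxel_size, grid$nx)
  iy <- axis_index(point[2], lo[2], grid$voxel_size, grid$ny)
  as.integer(iy * grid$nx + ix + 1)
}

#' Voxel a cell interacts with (position or front)
#'
#' A moving cell senses and degrades the voxel nearest to its *front*: the
#' point on its surface in the direction of motion, `x + R * d`. A
#' stationary cell (zero direction) uses the voxel nearest to its centre.
#' Fronts falling outside the lattice are clamped to the nearest in-domain
#' point (the domain should be sized so this is rare).
#'
#' @param cell A list or one-row data frame with `x`, `y`, `radius`,
#'   `dir_x`, `dir_y` (direction need not be normalised; only its direction
#'   is used).
#' @param grid An `ecm_grid`.
#' @return Integer linear voxel index.
#' @export
select_interaction_voxel <- function(cell, grid) {
  d <- c(cell$dir_x, cell$dir_y)
  nd <- sqrt(sum(d^2))
  pt <- c(cell$x, cell$y)
  if (nd > 0) {
    pt <- pt + cell$radius * d / nd
    lo <- grid$origin
    hi <- grid$origin + c(grid$nx, grid$ny) * grid$voxel_size
    pt <- pmin(pmax(pt, lo), hi)
  }
  voxel_of_point(grid, pt)
}

#' Degrade the ECM density of one voxel
#'
#' Exact one-step solution of `d rho / dt = -rate * rho`:
#' `rho <- rho * exp(-rate * dt)`. Unconditionally stable, keeps
#' `rho >= 0`, and agrees with forward Euler to first order at the model's
#' small rates.
#'
#' @param grid An `ecm_grid`.
#' @param voxel Linear voxel index (from [voxel_of_point()]).
#' @param rate Degradation rate (min^-1), `>= 0`.
#' @param dt Time step (min), `> 0`.
#' @return The grid with the voxel's density updated.
#' @export
degrade <- function(grid, voxel, rate, dt) {
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  grid$density[voxel] <- grid$density[voxel] * exp(-rate * dt)
  grid
}

#' Write / read an ECM grid as plain text
#'
#' The density matrix is written one lattice row (fixed `iy`) per line at
#' full precision, with a JSON header sidecar (`<path>.meta.json`) holding
#' the origin, voxel size and voxel counts, so the grid round-trips
#' losslessly.
#'
#' @param grid An `ecm_grid`.
#' @param path Output path for the density matrix.
#' @return `write_ecm_grid()` returns `path` invisibly; `read_ecm_grid()`
#'   returns the reconstructed `ecm_grid`.
#' @export
write_ecm_grid <- function(grid, path) {
  lines <- vapply(seq_len(grid$ny), function(iy) {
    paste(format(grid$density[, iy], digits = 17, trim = TRUE),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  meta <- list(origin = grid$origin, voxel_size = grid$voxel_size,
               nx = grid$nx, ny = grid$ny)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ecm_grid
#' @export
read_ecm_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  rows <- lapply(readLines(path), function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  dens <- matrix(unlist(rows), nrow = meta$nx, ncol = meta$ny)
  structure(
    list(origin = as.numeric(meta$origin), voxel_size = meta$voxel_size,
         nx = meta$nx, ny = meta$ny, density = dens),
    class = "ecm_grid"
  )
}
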
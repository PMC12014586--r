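# shared fixtures: tiny parameter sets and grids built in code

# parameters for fast, fully deterministic mechanics (no RNG consumed)
quiet_params <- function(...) {
  model_params(Tper = Inf, rdiv = 0, domain_half_width = 100,
               spheroid_diameter = 40, ...)
}

# a small grid with a known density pattern
small_grid <- function(hw = 50, voxel = 10, density = 1) {
  ecm_grid(domain_half_width = hw, voxel_size = voxel, density = density)
}

# brute-force nearest-voxel-centre search (independent oracle)
brute_nearest_voxel <- function(grid, point) {
  cx <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$voxel_size
  cy <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$voxel_size
  best <- Inf; best_idx <- NA_integer_
  for (iy in seq_len(grid$ny)) {
    for (ix in seq_len(grid$nx)) {
      d2 <- (cx[ix] - point[1])^2 + (cy[iy] - point[2])^2
      idx <- (iy - 1) * grid$nx + ix
      if (d2 < best - 1e-12) {
        best <- d2; best_idx <- as.integer(idx)
      }
    }
  }
  best_idx
}

# hexagonally packed patch of cells at a given spacing
hex_patch <- function(spacing, nring = 2, volume = 2494) {
  pts <- spheroidECM:::hex_disc_points(spacing, nring * spacing + 1e-6)
  cell_table(pts$x, pts$y, volume = volume)
}
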
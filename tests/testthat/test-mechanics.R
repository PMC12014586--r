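test_that("neighbour relation matches a brute-force pairwise scan", {
  set.seed(5)
  cells <- cell_table(runif(200, -80, 80), runif(200, -80, 80),
                      volume = runif(200, 1200, 2494))
  ra <- 1.25 * cells$radius
  for (id in sample(cells$id, 20)) {
    i <- match(id, cells$id)
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    expected <- cells$id[d < ra + ra[i] & cells$id != id]
    expect_setequal(neighbours(cells, id)$id, expected)
  }
  # symmetry: j in N(i) <=> i in N(j)
  cnt <- neighbour_counts(cells)
  for (i in seq_len(20)) {
    nb <- neighbours(cells, cells$id[i])
    for (j in nb$id) {
      expect_true(cells$id[i] %in% neighbours(cells, j)$id)
    }
    expect_identical(nrow(nb), cnt[i])
  }
})

test_that("an interior cell of a contact-spaced hexagonal patch has 6 neighbours", {
  r <- cell_radius(2494)
  cells <- hex_patch(spacing = 2 * r, nring = 2)
  centre_id <- cells$id[abs(cells$x) < 1e-9 & abs(cells$y) < 1e-9]
  expect_identical(nrow(neighbours(cells, centre_id)), 6L)
  # two distant cells are not neighbours
  far <- cell_table(c(0, 100), c(0, 0), volume = 2494)
  expect_identical(nrow(neighbours(far, 1)), 0L)
})

test_that("cell-cell velocities are pairwise antisymmetric and vanish without neighbours", {
  lone <- cell_table(0, 0, volume = 2494)
  v <- cell_cell_velocity(lone)
  expect_equal(c(v$vx, v$vy), c(0, 0))
  set.seed(9)
  for (sep in c(5, 10, 16, 20)) {
    pair <- cell_table(c(0, sep), c(0, 0), volume = 2494)
    v <- cell_cell_velocity(pair)
    expect_equal(v$vx[1], -v$vx[2])
    expect_equal(v$vy[1], -v$vy[2])
  }
})

test_that("repulsion switches off exactly at contact distance, adhesion persists", {
  r <- cell_radius(2494)
  pair <- cell_table(c(0, 2 * r), c(0, 0), volume = 2494)
  v <- cell_cell_velocity(pair, ccca = 0.4, cccr = 10)
  # at d = R_i + R_j only adhesion acts: cell 1 is pulled toward cell 2 (+x)
  expected <- 0.4 * (1 - 2 * r / (2 * 1.25 * r))^2
  expect_equal(v$vx[1], expected)
  expect_gt(v$vx[1], 0)
  # just inside contact, repulsion dominates: cell 1 pushed away (-x)
  pair2 <- cell_table(c(0, 1.8 * r), c(0, 0), volume = 2494)
  v2 <- cell_cell_velocity(pair2)
  expect_lt(v2$vx[1], 0)
})

test_that("cell-ECM velocity terms follow the density laws", {
  # adhesion speed is linear in density along the motility direction
  v <- cell_ecm_adhesion_velocity(1, 0, rho = 0.5, Srib = 0.7)
  expect_equal(c(v$vx, v$vy), c(1.4, 0))
  v0 <- cell_ecm_adhesion_velocity(0.6, 0.8, rho = 0, Srib = 0.7)
  expect_equal(c(v0$vx, v0$vy), c(0, 0))
  vmax <- cell_ecm_adhesion_velocity(0, 1, rho = 1, Srib = 0.7)
  expect_equal(vmax$vy, 4 * 0.7)
  # repulsion cancels a fraction rho of the driving velocity
  r0 <- cell_ecm_repulsion_velocity(2, 0, rho = 0)
  expect_equal(c(r0$vx, r0$vy), c(0, 0))
  r5 <- cell_ecm_repulsion_velocity(2, 0, rho = 0.5)
  expect_equal(r5$vx, -1)
  r1 <- cell_ecm_repulsion_velocity(3, -4, rho = 1)
  expect_equal(c(r1$vx, r1$vy), c(-3, 4))
  expect_error(cell_ecm_adhesion_velocity(1, 0, rho = 1.2, Srib = 1), "rho")
})

test_that("total cell-ECM speed peaks at rho = 0.5 with value Srib", {
  expect_equal(total_cell_ecm_speed(0.5, 0.7), 0.7)
  expect_equal(total_cell_ecm_speed(c(0, 1), 0.7), c(0, 0))
  expect_equal(total_cell_ecm_speed(0.25, 1), 0.75)
  rho <- seq(0, 1, by = 1e-4)
  s <- total_cell_ecm_speed(rho, 0.7)
  expect_equal(rho[which.max(s)], 0.5)
  expect_true(all(s <= 0.7 + 1e-12))
  # symmetry about the maximum
  expect_equal(total_cell_ecm_speed(0.3, 1), total_cell_ecm_speed(0.7, 1))
})

test_that("direction resampling has the prescribed frequency and is isotropic", {
  n <- 5e4
  cells <- cell_table(numeric(n), numeric(n), volume = 2494,
                      dir_x = 1, dir_y = 0)
  set.seed(123)
  out <- direction_update(cells, Tper = 10, dt = 0.1)
  changed <- out$dir_x != 1 | out$dir_y != 0
  p <- 0.01
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(changed) - p), 3 * se)
  # dt = Tper resamples every cell; Tper = Inf never does
  all_new <- direction_update(cells[1:1e4, ], Tper = 0.1, dt = 0.1)
  expect_true(all(abs(all_new$dir_x^2 + all_new$dir_y^2 - 1) < 1e-12))
  resultant <- c(mean(all_new$dir_x), mean(all_new$dir_y))
  expect_lt(sqrt(sum(resultant^2)), 0.05)
  frozen <- direction_update(cells[1:100, ], Tper = Inf, dt = 0.1)
  expect_identical(frozen$dir_x, rep(1, 100))
  expect_error(direction_update(cells[1:2, ], Tper = 0.05, dt = 0.1), "Tper")
})

test_that("position integration is forward Euler and checks the domain", {
  cells <- cell_table(0, 0, volume = 2494)
  for (i in 1:10) cells <- step_positions(cells, vx = 1, vy = 0, dt = 0.1)
  expect_equal(cells$x, 1)
  expect_equal(cells$y, 0)
  still <- step_positions(cell_table(3, -2, 2494), 0, 0, 0.1)
  expect_equal(c(still$x, still$y), c(3, -2))
  expect_error(step_positions(cell_table(99, 0, 2494), 100, 0, 1,
                              domain_half_width = 100), "domain")
})

test_that("an isolated cell in empty or full matrix does not move", {
  # degradation off so the wall density stays exactly at 1 over the step
  p <- quiet_params(S0 = 0.7, rdeg0 = 0)
  # rho = 0 everywhere: nothing to adhere to
  st <- init_spheroid(1, p)  # single cell
  st$grid$density[] <- 0
  st$cells$dir_x <- 1
  out <- mechanics_step(st$cells, st$grid, p)
  expect_equal(out$cells$x, st$cells$x)
  # rho = 1 everywhere: the matrix is a wall
  st$grid$density[] <- 1
  out2 <- mechanics_step(st$cells, st$grid, p)
  expect_equal(out2$cells$x, st$cells$x)
  expect_equal(out2$cells$y, st$cells$y)
})

test_that("with all interaction strengths zero the configuration is a fixed point", {
  p <- quiet_params(S0 = 0, ccca = 0, cccr = 0, rdeg0 = 0)
  st <- init_spheroid(40, p)
  out <- mechanics_step(st$cells, st$grid, p)
  expect_identical(out$cells$x, st$cells$x)
  expect_identical(out$cells$y, st$cells$y)
  expect_identical(out$grid$density, st$grid$density)
})

test_that("compiled engine reproduces the plain-R reference step", {
  # deterministic configuration: no resampling, no division, no growth
  p <- quiet_params(S0 = 0.5, rdeg0 = 0.01, growth_rate_k = 0)
  st <- init_spheroid(40, p)
  # give cells outward directions so motility and degradation engage
  ang <- atan2(st$cells$y, st$cells$x)
  ang[st$cells$x == 0 & st$cells$y == 0] <- 0
  st$cells$dir_x <- cos(ang)
  st$cells$dir_y <- sin(ang)

  ref_cells <- st$cells
  ref_grid <- st$grid
  n_steps <- 20
  for (i in seq_len(n_steps)) {
    out <- mechanics_step(ref_cells, ref_grid, p)
    ref_cells <- out$cells
    ref_grid <- out$grid
  }

  cpp_par <- list(
    ox = st$grid$origin[1], oy = st$grid$origin[2],
    voxel_size = p$voxel_size, nx = st$grid$nx, ny = st$grid$ny,
    dt_mech = p$dt_mech, n_steps = n_steps,
    steps_per_cell = as.integer(p$dt_cell / p$dt_mech),
    record_every_steps = n_steps,
    rdeg = degradation_rate(p$rdeg0, p$delta, p$rib),
    Srib = max_speed(p$S0, p$sigma, p$rib),
    Tper = p$Tper, rdiv = p$rdiv, Nmax = as.integer(p$Nmax),
    ccca = p$ccca, cccr = p$cccr,
    adhesion_radius_multiple = p$adhesion_radius_multiple,
    growth_rate_k = p$growth_rate_k, cell_volume_max = p$cell_volume_max,
    domain_half_width = p$domain_half_width
  )
  res <- spheroidECM:::sim_run_cpp(
    st$cells$x, st$cells$y, st$cells$volume,
    st$cells$dir_x, st$cells$dir_y, st$grid$density, cpp_par)
  expect_equal(res$cells$x, ref_cells$x, tolerance = 1e-12)
  expect_equal(res$cells$y, ref_cells$y, tolerance = 1e-12)
  expect_equal(as.vector(res$rho), as.vector(ref_grid$density),
               tolerance = 1e-12)
})
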
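test_that("raster area matches the analytic disk area and ignores overlaps", {
  expect_equal(raster_area(cell_table(numeric(0), numeric(0), numeric(0)),
                           c(-50, 50)), 0)
  one <- tibble::tibble(x = 0, y = 0, radius = 10)
  a1 <- raster_area(one, c(-50, 50), n = 5000)
  expect_equal(a1, pi * 100, tolerance = 0.01)
  # coincident disks count once
  two <- tibble::tibble(x = c(0, 0), y = c(0, 0), radius = c(10, 10))
  expect_identical(raster_area(two, c(-50, 50), n = 5000), a1)
  # monotone under adding a cell
  three <- tibble::tibble(x = c(0, 15), y = c(0, 0), radius = c(10, 10))
  expect_gte(raster_area(three, c(-50, 50), n = 2000),
             raster_area(one, c(-50, 50), n = 2000))
})

test_that("raster area converges to the exact union area with resolution", {
  set.seed(21)
  cells <- tibble::tibble(x = runif(12, -20, 20), y = runif(12, -20, 20),
                          radius = runif(12, 5, 10))
  errs <- vapply(c(1250, 2500, 5000), function(n) {
    raster_area(cells, c(-50, 50), n)
  }, numeric(1))
  # Richardson-style trend: successive refinements move by less
  expect_lt(abs(errs[3] - errs[2]), abs(errs[2] - errs[1]) + 1e-9)
  expect_equal(errs[2], errs[3], tolerance = 0.005)
})

test_that("relative growth normalises by the initial area", {
  expect_equal(relative_growth(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(relative_growth(c(100, 340)), c(1, 3.4))
  expect_equal(relative_growth(c(3, 6))[2], 2)
  expect_error(relative_growth(c(0, 1)), "positive")
})

test_that("Delaunay mean distance reproduces analytic cases", {
  side <- 7.5
  tri <- tibble::tibble(x = c(0, side, side / 2),
                        y = c(0, 0, side * sqrt(3) / 2))
  expect_equal(delaunay_mean_distance(tri), side)
  sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(delaunay_mean_distance(sq), (4 + sqrt(2)) / 5)
  # degenerate inputs yield a missing value, not an error
  expect_true(is.na(delaunay_mean_distance(tri[1:2, ])))
  line <- tibble::tibble(x = 1:5, y = 2 * (1:5))
  expect_true(is.na(delaunay_mean_distance(line)))
})

test_that("Delaunay mean distance matches an independent triangulation oracle", {
  # frozen reference values from an independent Delaunay implementation
  # (scipy.spatial) on fixed point sets
  p1 <- tibble::tibble(
    x = c(27.900929, -1.699049, 7.163862, 42.504889, 2.854017, -13.142243,
          -13.009764, 13.022334, 23.806205, -5.815386, 5.891769, 34.161597,
          47.259026, -31.809976, -5.318661, -49.425238, -0.992094, 37.078679,
          -6.343972, 4.362928, -26.94588, -13.007094, 15.287718, 12.33826,
          13.166394, -27.303601, -43.533653, -49.107058, -11.730307,
          22.143412, -45.011924, 15.21007, -27.676982, 46.273678, 46.508676,
          27.735942, -26.235142, -27.978193, -6.438955, 46.367904),
    y = c(-24.604535, -18.660921, 48.90953, -4.445432, -29.268288, 16.879937,
          -35.446945, -24.971227, 39.96008, 39.198756, 39.388208, -12.30263,
          24.58704, -4.840855, -39.99947, 37.967092, 26.173755, -30.046492,
          -45.505042, 25.289592, 41.596432, -31.720083, 25.14113, -10.228919,
          36.273708, 37.060068, 2.775982, -24.429188, 11.851623, -31.203421,
          35.431801, 39.347134, 10.980723, 13.636479, -24.646096, -3.241444,
          -35.109347, 23.652669, 20.888862, -36.350415))
  expect_equal(delaunay_mean_distance(p1), 19.87968097729545, tolerance = 1e-9)
  p2 <- tibble::tibble(
    x = c(8.289395, 0.309346, 3.186008, 4.9518, 3.781239, 7.8321, 3.686057,
          2.591011, 5.663028, 1.409161, 6.83542, 6.682229, 3.609717,
          5.122773, 4.648812),
    y = c(2.087603, 7.338888, 6.20117, 0.174473, 3.531367, 5.383989,
          3.331284, 1.093004, 8.642513, 9.300035, 6.72527, 8.126858,
          3.976461, 8.014035, 3.303278))
  expect_equal(delaunay_mean_distance(p2), 2.6663277944925903, tolerance = 1e-9)
})

test_that("Delaunay mean distance is invariant under rigid motions and approaches the lattice spacing", {
  set.seed(33)
  pts <- tibble::tibble(x = runif(60, -30, 30), y = runif(60, -30, 30))
  base <- delaunay_mean_distance(pts)
  th <- 0.83
  rot <- tibble::tibble(x = cos(th) * pts$x - sin(th) * pts$y + 12.5,
                        y = sin(th) * pts$x + cos(th) * pts$y - 3.75)
  expect_equal(delaunay_mean_distance(rot), base, tolerance = 1e-8)
  # hexagonal lattice: a clean hexagonal patch triangulates into unit
  # triangles (mean edge = spacing); a large ragged-boundary disc stays
  # close to the spacing, with only hull edges deviating
  a <- 10
  m_clean <- delaunay_mean_distance(hex_patch(a, nring = 4)[, c("x", "y")])
  expect_equal(m_clean, a, tolerance = 1e-8)
  m_big <- delaunay_mean_distance(hex_patch(a, nring = 16)[, c("x", "y")])
  expect_equal(m_big, a, tolerance = 0.03)
})

test_that("replicate aggregation computes means and interpolated quartiles", {
  one <- tibble::tibble(replicate = 1, time_min = c(0, 60),
                        cell_count = c(10, 12))
  agg1 <- aggregate_replicates(one)
  expect_equal(agg1$mean, agg1$p25)
  expect_equal(agg1$mean, agg1$p75)
  four <- tidyr::expand_grid(replicate = 1:4, time_min = 0)
  four$growth <- c(1, 2, 3, 4)
  agg4 <- aggregate_replicates(four)
  expect_equal(agg4$mean, 2.5)
  expect_equal(agg4$p25, 1.75)  # linear interpolation of order statistics
  expect_equal(agg4$p75, 3.25)
  # permutation invariance
  shuffled <- four[c(3, 1, 4, 2), ]
  expect_equal(aggregate_replicates(shuffled), agg4)
  # ragged time grids are rejected
  bad <- tibble::tibble(replicate = c(1, 1, 2), time_min = c(0, 60, 0),
                        cell_count = c(1, 2, 3))
  expect_error(aggregate_replicates(bad), "ragged|mismatched")
})
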
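# Terrain metrics against analytic surfaces and independent per-cell oracles.

# planes built in meters using each row's own zonal spacing, so analytic
# slopes/aspects hold exactly under the geographic-degrees convention
plane_grid <- function(nr, nc, east_mpm = 0, north_mpm = 0, cell = 0.01) {
  g <- bgrid(matrix(0, nr, nc), -5, 0.05, cell)
  mt <- list(dx = 111.195e3 * cell * cos(grid_lats(g) * pi / 180),
             dy = 111.195e3 * cell)
  z <- outer(seq_len(nr), seq_len(nc), function(r, c) {
    east_mpm * (c - 1) * mt$dx[1] + north_mpm * (nr - r) * mt$dy
  })
  grid_like(g, z)
}

test_that("slope is zero on flat seafloor and 45 degrees on a unit-gradient plane", {
  flat <- bgrid(matrix(-2000, 6, 6), 0, 0.03, 0.01)
  s <- slope_4cell(flat)
  expect_true(all(s$values[2:5, 2:5] == 0))
  expect_true(all(is.na(s$values[1, ])))  # incomplete windows are nodata

  north45 <- plane_grid(7, 7, north_mpm = 1)
  s2 <- slope_4cell(north45)
  expect_equal(s2$values[2:6, 2:6], matrix(45, 5, 5), tolerance = 1e-9)
  expect_error(slope_4cell(bgrid(matrix(0, 2, 5), 0, 0, 0.01)), "3x3")
})

test_that("slope matches the per-cell finite-difference oracle on random terrain", {
  for (seed in 1:3) {
    g <- random_grid(7, 9, seed = seed)
    expect_equal(slope_4cell(g)$values, oracle_slope(g), tolerance = 1e-9)
  }
})

test_that("aspect indices point downslope and satisfy the unit-circle identity", {
  east_dip <- plane_grid(6, 6, east_mpm = -0.3)  # deepens eastward
  a <- aspect_indices(east_dip)
  expect_equal(a$eastness$values[3, 3], 1, tolerance = 1e-6)
  expect_equal(a$northness$values[3, 3], 0, tolerance = 1e-6)

  north_dip <- plane_grid(6, 6, north_mpm = -0.3)
  a2 <- aspect_indices(north_dip)
  expect_equal(a2$eastness$values[3, 3], 0, tolerance = 1e-6)
  expect_equal(a2$northness$values[3, 3], 1, tolerance = 1e-6)

  g <- random_grid(9, 9, seed = 4)
  a3 <- aspect_indices(g)
  inner <- 2:8
  expect_equal(a3$eastness$values[inner, inner]^2 + a3$northness$values[inner, inner]^2,
               matrix(1, 7, 7), tolerance = 1e-9)
  o <- oracle_aspect(g)
  expect_equal(a3$eastness$values, o$eastness, tolerance = 1e-9)
  expect_equal(a3$northness$values, o$northness, tolerance = 1e-9)

  flat <- bgrid(matrix(-1000, 5, 5), 0, 0.02, 0.01)
  expect_true(all(is.na(aspect_indices(flat)$eastness$values)))
})

test_that("curvatures vanish on planes and are positive on a convex dome", {
  tilted <- plane_grid(7, 7, east_mpm = 0.2, north_mpm = -0.1)
  cv <- curvature(tilted)
  inner <- 2:6
  expect_equal(cv$general$values[inner, inner], matrix(0, 5, 5), tolerance = 1e-12)
  expect_equal(cv$cross_sectional$values[inner, inner], matrix(0, 5, 5), tolerance = 1e-12)
  expect_equal(cv$longitudinal$values[inner, inner], matrix(0, 5, 5), tolerance = 1e-12)

  # paraboloid dome z = -(x^2 + y^2): convex, so positive general curvature
  g <- bgrid(matrix(0, 9, 9), -5, 0.041, 0.01)
  d <- 111.195e3 * 0.01
  z <- outer(seq_len(9), seq_len(9), function(r, c) {
    -(((c - 5) * d)^2 + ((5 - r) * d)^2) * 1e-4
  })
  dome <- grid_like(g, z)
  cv2 <- curvature(dome)
  expect_gt(cv2$general$values[5, 5], 0)
})

test_that("curvatures match the least-squares quadratic-fit oracle per cell", {
  g <- random_grid(9, 9, seed = 7)
  cv <- curvature(g)
  o <- oracle_curvature(g)
  expect_equal(cv$general$values, o$general, tolerance = 1e-8)
  expect_equal(cv$cross_sectional$values, o$cross_sectional, tolerance = 1e-8)
  expect_equal(cv$longitudinal$values, o$longitudinal, tolerance = 1e-8)
  # directional curvatures always partition the general curvature
  inner <- 2:8
  expect_equal(
    cv$cross_sectional$values[inner, inner] + cv$longitudinal$values[inner, inner],
    cv$general$values[inner, inner],
    tolerance = 1e-10
  )
})

test_that("surface-ratio roughness is 1 on flat ground and sqrt(2) on a 45-degree plane", {
  flat <- bgrid(matrix(-3000, 6, 6), 0, 0.03, 0.01)
  r <- roughness_surface_ratio(flat)
  expect_equal(r$values[2:5, 2:5], matrix(1, 4, 4), tolerance = 1e-12)

  p45 <- plane_grid(7, 7, north_mpm = 1)
  r2 <- roughness_surface_ratio(p45)
  expect_equal(r2$values[3, 3], sqrt(2), tolerance = 1e-9)
})

test_that("roughness matches the explicit triangulated-area oracle and is >= 1", {
  for (seed in 1:3) {
    g <- random_grid(8, 8, seed = 20 + seed, scale = 300)
    r <- roughness_surface_ratio(g)
    expect_equal(r$values, oracle_roughness(g), tolerance = 1e-9)
    expect_true(all(r$values >= 1, na.rm = TRUE))
  }
})

test_that("TPI is zero on flat terrain and flags a lone peak", {
  flat <- bgrid(matrix(-2500, 11, 11), 0, 0.055, 0.01)
  t1 <- tpi(flat, 3000)
  expect_true(all(t1$values == 0, na.rm = TRUE))

  m <- matrix(-3000, 11, 11); m[6, 6] <- -2000
  peak <- bgrid(m, 0, 0.055, 0.01)
  t2 <- tpi(peak, 4000)
  expect_gt(t2$values[6, 6], 0)
  expect_lt(t2$values[6, 5], 0)  # neighbor sees the peak raise its surroundings
  expect_error(tpi(flat, 100), "smaller than one cell")
})

test_that("TPI matches a brute-force disk-mean oracle", {
  g <- random_grid(21, 21, seed = 31)
  radius <- 3 * 111.195e3 * 0.01  # three cells
  expect_equal(tpi(g, radius)$values, oracle_tpi(g, radius), tolerance = 1e-9)
})

test_that("VRM is zero for flat and uniformly tilted terrain and bounded in [0,1]", {
  flat <- bgrid(matrix(-2000, 9, 9), 0, 0.04, 0.01)
  expect_true(all(vrm(flat, 3)$values == 0, na.rm = TRUE))

  tilt <- plane_grid(9, 9, north_mpm = 0.5)  # constant tilt: parallel normals
  v <- vrm(tilt, 3)
  expect_true(all(abs(v$values) < 1e-12, na.rm = TRUE))

  g <- random_grid(15, 15, seed = 5)
  v2 <- vrm(g, 5)
  expect_true(all(v2$values >= 0 & v2$values <= 1, na.rm = TRUE))
  expect_error(vrm(g, 4), "odd")
  expect_error(vrm(g, 1), "odd|>= 3")
})

test_that("VRM matches the brute-force vector-sum oracle", {
  for (seed in 1:2) {
    g <- random_grid(10, 10, seed = 40 + seed)
    expect_equal(vrm(g, 3)$values, oracle_vrm(g, 3), tolerance = 1e-9)
  }
})

test_that("all metrics are invariant to vertical translation of the seafloor", {
  g <- random_grid(12, 12, seed = 55)
  g_up <- grid_like(g, g$values + 1234.5)
  expect_equal(slope_4cell(g)$values, slope_4cell(g_up)$values, tolerance = 1e-9)
  expect_equal(curvature(g)$general$values, curvature(g_up)$general$values,
               tolerance = 1e-9)
  expect_equal(roughness_surface_ratio(g)$values,
               roughness_surface_ratio(g_up)$values, tolerance = 1e-9)
  radius <- 2.5 * 111.195e3 * 0.01
  expect_equal(tpi(g, radius)$values, tpi(g_up, radius)$values, tolerance = 1e-9)
  expect_equal(vrm(g, 3)$values, vrm(g_up, 3)$values, tolerance = 1e-9)
})

test_that("terrain_suite assembles the configured multi-scale layer set", {
  g <- random_grid(15, 15, seed = 66)
  radius <- 111.195e3 * 0.01
  st <- terrain_suite(g, tpi_radii_m = c(radius * 2, radius * 4),
                      vrm_neighborhoods = c(3, 5))
  expect_setequal(
    names(st),
    c("slope", "eastness", "northness", "curvature_general",
      "curvature_cross_sectional", "curvature_longitudinal", "roughness",
      sprintf("tpi_%g", c(radius * 2, radius * 4)), "vrm_3", "vrm_5")
  )
})
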
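# Stack alignment, seafloor upscaling, correlation screening and point
# validation.

make_layered <- function(fun, levels = c(0, 1000, 2000, 4000), nrc = 4,
                         origin = c(0, 0), cell = 0.1, noise = NULL) {
  arr <- array(NA_real_, c(length(levels), nrc, nrc))
  for (l in seq_along(levels)) {
    arr[l, , ] <- fun(levels[l]) + if (is.null(noise)) 0 else noise
  }
  layered_field(arr, levels, origin[1], origin[2], cell, name = "f")
}

test_that("env_stack enforces alignment and unique layer names", {
  a <- bgrid(matrix(1, 4, 4), 0, 0, 0.1)
  b <- bgrid(matrix(2, 4, 4), 0, 0, 0.1)
  st <- env_stack(list(x = a, y = b))
  expect_equal(names(st), c("x", "y"))
  off <- bgrid(matrix(2, 4, 4), 0.05, 0, 0.1)
  expect_error(env_stack(list(x = a, y = off)), "aligned")
  expect_error(env_stack(list(a, b)), "names")
})

test_that("a constant layered field upscales to the same constant", {
  fld <- make_layered(function(z) 42)
  bathy <- bgrid(matrix(-1500, 8, 8), 0.02, -0.02, 0.02)
  up <- upscale_to_seafloor(fld, bathy)
  expect_equal(up$values, matrix(42, 8, 8), tolerance = 1e-12)
})

test_that("a depth-linear horizontally-constant field upscales exactly", {
  a <- 3; b <- 0.0125
  fld <- make_layered(function(z) a + b * z)
  set.seed(8)
  depths <- -matrix(runif(64, 100, 3900), 8, 8)
  bathy <- bgrid(depths, 0.02, -0.02, 0.02)
  up <- upscale_to_seafloor(fld, bathy)
  expect_equal(up$values, a + b * (-depths), tolerance = 1e-12)
  # clamping below the deepest level
  deep <- bgrid(matrix(-9000, 4, 4), 0.05, -0.05, 0.02)
  expect_equal(upscale_to_seafloor(fld, deep)$values,
               matrix(a + b * 4000, 4, 4), tolerance = 1e-12)
})

test_that("a 2x2x2 toy reproduces hand-computed bilinear + vertical interpolation", {
  # coarse 2x2 grid, centers at lon 0, 0.2 and lat 0, -0.2; two levels
  arr <- array(NA_real_, c(2, 2, 2))
  # level 1000: NW=1 NE=2 SW=3 SE=4 (rows north->south, cols west->east)
  arr[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  arr[2, , ] <- matrix(c(5, 6, 7, 8), 2, 2, byrow = TRUE)  # level 3000
  fld <- layered_field(arr, c(1000, 3000), 0, 0, 0.2)
  # one fine cell at lon 0.05, lat -0.1, depth 1500
  bathy <- bgrid(matrix(-1500, 1, 1), 0.05, -0.1, 0.01)
  # hand computation: tx = 0.25 (east), ty = 0.5 (south)
  lev1 <- (1 - 0.5) * ((1 - 0.25) * 1 + 0.25 * 2) + 0.5 * ((1 - 0.25) * 3 + 0.25 * 4)
  lev2 <- (1 - 0.5) * ((1 - 0.25) * 5 + 0.25 * 6) + 0.5 * ((1 - 0.25) * 7 + 0.25 * 8)
  expected <- lev1 + (1500 - 1000) / 2000 * (lev2 - lev1)
  up <- upscale_to_seafloor(fld, bathy)
  expect_equal(up$values[1, 1], expected, tolerance = 1e-12)
})

test_that("layered fields round-trip through the plain-text format", {
  set.seed(12)
  arr <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  fld <- layered_field(arr, c(0, 500, 1500), -80, -20, 0.5, name = "oxy")
  path <- withr::local_tempfile(fileext = ".txt")
  write_layered_field(fld, path)
  fld2 <- read_layered_field(path)
  expect_equal(fld2$values, fld$values, tolerance = 1e-7)
  expect_equal(fld2$depth_levels, fld$depth_levels)
  expect_equal(fld2$cell_size, fld$cell_size, tolerance = 1e-12)
})

test_that("correlation matrix has exact structure and respects masking", {
  set.seed(2)
  base <- matrix(rnorm(400), 20, 20)
  g1 <- bgrid(base, 0, 0, 0.01)
  g2 <- bgrid(-base, 0, 0, 0.01)
  g3 <- bgrid(matrix(rnorm(400), 20, 20), 0, 0, 0.01)
  cm <- correlation_matrix(env_stack(list(a = g1, b = g2, c = g3)))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm["a", "b"], -1)
  expect_true(isSymmetric(cm))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_error(correlation_matrix(env_stack(list(a = g1))), "2 layers")

  # affine rescaling of a layer leaves correlations unchanged
  g1s <- bgrid(3 * base + 7, 0, 0, 0.01)
  cm2 <- correlation_matrix(env_stack(list(a = g1s, b = g2, c = g3)))
  expect_equal(cm2, cm, tolerance = 1e-12)
})

test_that("independent random layers are near-uncorrelated at 10^4 cells", {
  set.seed(77)
  g1 <- bgrid(matrix(rnorm(10000), 100, 100), 0, 0, 0.01)
  g2 <- bgrid(matrix(rnorm(10000), 100, 100), 0, 0, 0.01)
  cm <- correlation_matrix(env_stack(list(a = g1, b = g2)))
  expect_lt(abs(cm["a", "b"]), 0.05)
})

test_that("variable clustering merges near-duplicates first with sane heights", {
  cm <- diag(3)
  dimnames(cm) <- list(c("v1", "v2", "v3"), c("v1", "v2", "v3"))
  cm["v1", "v2"] <- cm["v2", "v1"] <- 0.99
  hc <- cluster_variables(cm)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("v1", "v2"))

  # identical variables merge at height 0
  cm2 <- matrix(1, 2, 2); dimnames(cm2) <- list(c("a", "b"), c("a", "b"))
  expect_equal(cluster_variables(cm2)$height, 0)

  # average linkage on a random correlation matrix has non-decreasing heights
  set.seed(5)
  X <- matrix(rnorm(600), 100, 6)
  cm3 <- stats::cor(X)
  expect_true(all(diff(cluster_variables(cm3)$height) >= -1e-12))
  expect_error(cluster_variables(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("the correlation screen keeps the highest-priority member of each pair", {
  cm <- diag(4)
  nms <- c("poc", "silicate", "slope", "tpi")
  dimnames(cm) <- list(nms, nms)
  cm["poc", "silicate"] <- cm["silicate", "poc"] <- -0.85
  sc <- screen_variables(cm, threshold = 0.7, keep_priority = nms)
  expect_equal(sc$kept, c("poc", "slope", "tpi"))
  expect_equal(sc$dropped, "silicate")
  expect_equal(nrow(sc$flagged_pairs), 1)
  expect_equal(sc$flagged_pairs$r, -0.85)

  # priority reversal flips which variable survives
  sc2 <- screen_variables(cm, threshold = 0.7,
                          keep_priority = c("silicate", "poc", "slope", "tpi"))
  expect_true("silicate" %in% sc2$kept && !"poc" %in% sc2$kept)

  # nothing above threshold: all kept; kept set never contains a hot pair
  ident <- diag(4); dimnames(ident) <- list(nms, nms)
  sc3 <- screen_variables(ident, threshold = 0.7, keep_priority = nms)
  expect_equal(sc3$kept, nms)
  expect_error(screen_variables(cm, 0.7, c("poc", "silicate")), "order exactly")
  set.seed(31)
  X <- matrix(rnorm(500), 100, 5)
  X[, 2] <- X[, 1] * 0.95 + rnorm(100, sd = 0.1)
  cmr <- stats::cor(X); dimnames(cmr) <- list(letters[1:5], letters[1:5])
  scr <- screen_variables(cmr, 0.7, letters[1:5])
  sub <- cmr[scr$kept, scr$kept]
  expect_true(all(abs(sub[upper.tri(sub)]) <= 0.7))
})

test_that("point validation filters to near-bottom samples and recovers r = 1", {
  set.seed(14)
  g <- bgrid(matrix(rnorm(100, 10, 2), 10, 10), 0, 0, 0.05)
  tb <- as_tibble(g)
  n <- 30
  idx <- sample.int(nrow(tb), n)
  samples <- tibble::tibble(
    lon = tb$lon[idx], lat = tb$lat[idx],
    bottom_depth_m = runif(n, 1000, 3000)
  )
  samples$sample_depth_m <- samples$bottom_depth_m - runif(n, 0, 120)
  samples$value <- tb$value[idx]
  res <- validate_against_points(g, samples, near_bottom_tolerance_m = 50)
  n_expected <- sum(samples$bottom_depth_m - samples$sample_depth_m <= 50)
  expect_equal(res$n, n_expected)
  expect_equal(res$r, 1, tolerance = 1e-12)

  # random sample values decorrelate from the grid
  samples2 <- samples
  samples2$value <- rnorm(n)
  samples2$sample_depth_m <- samples2$bottom_depth_m
  res2 <- validate_against_points(g, samples2, 50)
  expect_equal(res2$n, n)
  expect_lt(abs(res2$r), 0.6)

  # no qualifying samples: empty result, not an error
  far <- samples
  far$sample_depth_m <- far$bottom_depth_m - 500
  res3 <- validate_against_points(g, far, 50)
  expect_equal(res3$n, 0L)
  expect_true(is.na(res3$r))
})
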
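# Terrain predictors derived from a bathymetry grid.
#
# All focal operations return nodata where the window is incomplete (no
# padding beyond the grid) and propagate nodata from masked inputs. Degrees
# are converted to meters with a constant 111,195 m/degree meridionally and a
# per-row cos(latitude) factor zonally.

# meters per cell step: dx varies by row latitude, dy is constant
cell_meters <- function(grid) {
  list(
    dx = KM_PER_DEGREE * 1000 * grid$cell_size * cos(grid_lats(grid) * pi / 180),
    dy = KM_PER_DEGREE * 1000 * grid$cell_size
  )
}

check_focal_input <- function(bathy) {
  stopifnot(inherits(bathy, "bgrid"))
  if (nrow(bathy$values) < 3 || ncol(bathy$values) < 3) {
    stop("terrain metrics need a grid of at least 3x3 cells")
  }
}

# shifted copies of the interior window: sh(dr, dc)[r, c] = z[r + dr, c + dc]
# evaluated on interior cells only; returns an (nr-2) x (nc-2) matrix
interior_shift <- function(z, dr, dc) {
  nr <- nrow(z); nc <- ncol(z)
  z[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc), drop = FALSE]
}

# central-difference gradient (fx east, fy north) on interior cells, in m/m
gradient_4cell <- function(bathy) {
  check_focal_input(bathy)
  z <- bathy$values
  mt <- cell_meters(bathy)
  dx_int <- mt$dx[2:(nrow(z) - 1)]
  fx <- (interior_shift(z, 0, 1) - interior_shift(z, 0, -1)) / (2 * dx_int)
  fy <- (interior_shift(z, -1, 0) - interior_shift(z, 1, 0)) / (2 * mt$dy)
  list(fx = fx, fy = fy)
}

pad_interior <- function(bathy, interior, name) {
  m <- matrix(NA_real_, nrow(bathy$values), ncol(bathy$values))
  m[2:(nrow(m) - 1), 2:(ncol(m) - 1)] <- interior
  grid_like(bathy, m, name = name)
}

#' Slope in degrees (4-cell method)
#'
#' Central differences over the four rook neighbors give the local gradient;
#' slope = atan(sqrt(fx^2 + fy^2)) in degrees. Run lengths are converted from
#' degrees to meters at each cell's latitude.
#'
#' @param bathy Bathymetry `bgrid` (meters, negative down).
#' @return A `bgrid` of slope in degrees, in [0, 90); border cells nodata.
#' @export
slope_4cell <- function(bathy) {
  g <- gradient_4cell(bathy)
  pad_interior(bathy, atan(sqrt(g$fx^2 + g$fy^2)) * 180 / pi, "slope")
}

#' Aspect as eastness and northness indices
#'
#' Aspect is the downslope compass direction; eastness = sin(aspect) and
#' northness = cos(aspect) decompose it into two continuous indices in
#' [-1, 1]. Flat cells (zero gradient) have no aspect and are masked.
#'
#' @param bathy Bathymetry `bgrid`.
#' @return A list of two `bgrid`s: `eastness`, `northness`.
#' @export
aspect_indices <- function(bathy) {
  g <- gradient_4cell(bathy)
  mag <- sqrt(g$fx^2 + g$fy^2)
  mag[mag == 0] <- NA_real_  # flat: aspect undefined
  list(
    eastness = pad_interior(bathy, -g$fx / mag, "eastness"),
    northness = pad_interior(bathy, -g$fy / mag, "northness")
  )
}

# Evans 6-parameter quadratic fit z = a x^2 + b y^2 + c xy + d x + e y + f
# over the 3x3 window (x east, y north, in meters); closed-form least squares
evans_coefficients <- function(bathy) {
  check_focal_input(bathy)
  z <- bathy$values
  mt <- cell_meters(bathy)
  gx <- mt$dx[2:(nrow(z) - 1)]; gy <- mt$dy
  z1 <- interior_shift(z, -1, -1); z2 <- interior_shift(z, -1, 0); z3 <- interior_shift(z, -1, 1)
  z4 <- interior_shift(z, 0, -1);  z5 <- interior_shift(z, 0, 0);  z6 <- interior_shift(z, 0, 1)
  z7 <- interior_shift(z, 1, -1);  z8 <- interior_shift(z, 1, 0);  z9 <- interior_shift(z, 1, 1)
  list(
    a = ((z1 + z3 + z4 + z6 + z7 + z9) / 6 - (z2 + z5 + z8) / 3) / gx^2,
    b = ((z1 + z2 + z3 + z7 + z8 + z9) / 6 - (z4 + z5 + z6) / 3) / gy^2,
    c = (z3 + z7 - z1 - z9) / (4 * gx * gy),
    d = (z3 + z6 + z9 - z1 - z4 - z7) / (6 * gx),
    e = (z1 + z2 + z3 - z7 - z8 - z9) / (6 * gy)
  )
}

#' General, cross-sectional and longitudinal curvature
#'
#' A quadratic surface (Evans method) is fit to each 3x3 window; curvatures
#' are read off the fitted coefficients. Sign convention: positive = convex
#' (domes and crests), negative = concave. Longitudinal curvature bends the
#' surface along the slope direction, cross-sectional perpendicular to it;
#' they sum to the general curvature. On (near-)flat cells where the slope
#' direction is undefined, both directional curvatures fall back to half the
#' general curvature. Units: 1/m.
#'
#' @param bathy Bathymetry `bgrid`.
#' @return A list of three `bgrid`s: `general`, `cross_sectional`,
#'   `longitudinal`.
#' @export
curvature <- function(bathy) {
  co <- evans_coefficients(bathy)
  g2 <- co$d^2 + co$e^2
  general <- -2 * (co$a + co$b)
  longi <- -2 * (co$a * co$d^2 + co$c * co$d * co$e + co$b * co$e^2) / g2
  cross <- -2 * (co$a * co$e^2 - co$c * co$d * co$e + co$b * co$d^2) / g2
  flat <- !is.na(g2) & g2 < 1e-24
  longi[flat] <- general[flat] / 2
  cross[flat] <- general[flat] / 2
  list(
    general = pad_interior(bathy, general, "curvature_general"),
    cross_sectional = pad_interior(bathy, cross, "curvature_cross_sectional"),
    longitudinal = pad_interior(bathy, longi, "curvature_longitudinal")
  )
}

#' Surface-ratio roughness (8-triangle method)
#'
#' The ratio of true surface area to planimetric area over each cell. The
#' surface is triangulated from the cell center to the midpoints of the
#' segments joining it to its 8 neighbors (Jenness construction): the eight
#' 3D triangle footprints tile exactly one cell, so the ratio is >= 1, with
#' larger values on more complex terrain.
#'
#' @param bathy Bathymetry `bgrid`.
#' @return A `bgrid` of ratios (>= 1); border cells nodata.
#' @export
roughness_surface_ratio <- function(bathy) {
  check_focal_input(bathy)
  z <- bathy$values
  mt <- cell_meters(bathy)
  nr_i <- nrow(z) - 2
  dx <- matrix(mt$dx[2:(nrow(z) - 1)], nrow = nr_i, ncol = ncol(z) - 2)
  dy <- mt$dy
  # neighbor offsets in cyclic order starting north
  steps <- list(
    c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
  )
  zc <- interior_shift(z, 0, 0)
  # midpoint coordinates (relative to cell center) and elevations per direction
  mx <- vector("list", 8); my <- vector("list", 8); mz <- vector("list", 8)
  for (k in 1:8) {
    dr <- steps[[k]][1]; dc <- steps[[k]][2]
    mx[[k]] <- dc * dx / 2
    my[[k]] <- matrix(-dr * dy / 2, nrow = nr_i, ncol = ncol(z) - 2)
    mz[[k]] <- (zc + interior_shift(z, dr, dc)) / 2
  }
  surf <- 0
  for (k in 1:8) {
    k2 <- if (k == 8) 1 else k + 1
    # triangle (center, m_k, m_k2): area = |u x v| / 2 with u, v edge vectors
    ux <- mx[[k]]; uy <- my[[k]]; uz <- mz[[k]] - zc
    vx <- mx[[k2]]; vy <- my[[k2]]; vz <- mz[[k2]] - zc
    cxv <- uy * vz - uz * vy
    cyv <- uz * vx - ux * vz
    czv <- ux * vy - uy * vx
    surf <- surf + sqrt(cxv^2 + cyv^2 + czv^2) / 2
  }
  pad_interior(bathy, surf / (dx * dy), "roughness")
}

#' Topographic position index (TPI)
#'
#' TPI = cell elevation minus the mean elevation of all cells whose centers
#' lie within `radius_m` (a full disk, center excluded). Positive values mark
#' locally elevated features (summits, ridges), negative values depressions.
#' Cells whose disk extends beyond the grid, or covers any masked cell, are
#' nodata.
#'
#' @param bathy Bathymetry `bgrid`.
#' @param radius_m Neighborhood radius in meters (>= one cell's metric width).
#' @return A `bgrid` of TPI values (meters).
#' @export
tpi <- function(bathy, radius_m) {
  check_focal_input(bathy)
  z <- bathy$values
  mt <- cell_meters(bathy)
  if (radius_m < min(min(mt$dx), mt$dy)) {
    stop("tpi radius_m is smaller than one cell")
  }
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  max_dr <- floor(radius_m / mt$dy)
  for (r in seq_len(nr)) {
    dxr <- mt$dx[r]
    max_dc <- floor(radius_m / dxr)
    # disk offsets at this row's latitude scaling
    offs <- expand.grid(dr = -max_dr:max_dr, dc = -max_dc:max_dc)
    keep <- (offs$dr * mt$dy)^2 + (offs$dc * dxr)^2 <= radius_m^2
    keep <- keep & !(offs$dr == 0 & offs$dc == 0)
    offs <- offs[keep, , drop = FALSE]
    if (nrow(offs) == 0) next
    for (c in seq_len(nc)) {
      rr <- r + offs$dr; cc <- c + offs$dc
      if (any(rr < 1 | rr > nr | cc < 1 | cc > nc)) next  # incomplete window
      vals <- z[cbind(rr, cc)]
      if (anyNA(vals) || is.na(z[r, c])) next
      out[r, c] <- z[r, c] - mean(vals)
    }
  }
  grid_like(bathy, out, name = sprintf("tpi_%gm", radius_m))
}

#' Vector ruggedness measure (VRM)
#'
#' Terrain heterogeneity decoupled from steepness. Each cell's 3x3
#' slope/aspect defines a unit normal (x = sin(slope) sin(aspect),
#' y = sin(slope) cos(aspect), z = cos(slope)); over an n x n window the
#' resultant magnitude |R| of those normals gives VRM = 1 - |R| / n^2,
#' in [0, 1], with 0 for uniform terrain (flat or a constant tilt).
#'
#' @param bathy Bathymetry `bgrid`.
#' @param neighborhood_n Odd window size >= 3 (cells per side).
#' @return A `bgrid` of VRM values.
#' @export
vrm <- function(bathy, neighborhood_n) {
  if (neighborhood_n < 3 || neighborhood_n %% 2 != 1) {
    stop("vrm neighborhood_n must be odd and >= 3")
  }
  check_focal_input(bathy)
  g <- gradient_4cell(bathy)
  slope_r <- atan(sqrt(g$fx^2 + g$fy^2))
  mag <- sqrt(g$fx^2 + g$fy^2)
  east <- ifelse(mag > 0, -g$fx / mag, 0)
  north <- ifelse(mag > 0, -g$fy / mag, 0)
  nr <- nrow(bathy$values); nc <- ncol(bathy$values)
  nx <- matrix(NA_real_, nr, nc); ny <- nx; nz <- nx
  nx[2:(nr - 1), 2:(nc - 1)] <- sin(slope_r) * east
  ny[2:(nr - 1), 2:(nc - 1)] <- sin(slope_r) * north
  nz[2:(nr - 1), 2:(nc - 1)] <- cos(slope_r)
  h <- (neighborhood_n - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  lo_r <- 1 + h; hi_r <- nr - h; lo_c <- 1 + h; hi_c <- nc - h
  if (lo_r > hi_r || lo_c > hi_c) {
    return(grid_like(bathy, out, name = sprintf("vrm_%d", neighborhood_n)))
  }
  for (r in lo_r:hi_r) {
    for (c in lo_c:hi_c) {
      wr <- (r - h):(r + h); wc <- (c - h):(c + h)
      sx <- nx[wr, wc]; sy <- ny[wr, wc]; sz <- nz[wr, wc]
      if (anyNA(sz)) next
      res <- sqrt(sum(sx)^2 + sum(sy)^2 + sum(sz)^2)
      out[r, c] <- 1 - res / neighborhood_n^2
    }
  }
  grid_like(bathy, out, name = sprintf("vrm_%d", neighborhood_n))
}

#' Compute a standard suite of terrain predictors
#'
#' Convenience wrapper producing the usual layer set: slope, eastness,
#' northness, the three curvatures, roughness, and any requested TPI radii
#' (meters) and VRM neighborhoods (cells).
#'
#' @param bathy Bathymetry `bgrid`.
#' @param tpi_radii_m Numeric vector of TPI radii in meters.
#' @param vrm_neighborhoods Integer vector of odd VRM window sizes.
#' @return An `env_stack` of terrain layers.
#' @export
terrain_suite <- function(bathy, tpi_radii_m = numeric(), vrm_neighborhoods = integer()) {
  asp <- aspect_indices(bathy)
  cur <- curvature(bathy)
  layers <- c(
    list(
      slope = slope_4cell(bathy),
      eastness = asp$eastness,
      northness = asp$northness,
      curvature_general = cur$general,
      curvature_cross_sectional = cur$cross_sectional,
      curvature_longitudinal = cur$longitudinal,
      roughness = roughness_surface_ratio(bathy)
    ),
    stats::setNames(
      lapply(tpi_radii_m, function(r) tpi(bathy, r)),
      sprintf("tpi_%g", tpi_radii_m)
    ),
    stats::setNames(
      lapply(vrm_neighborhoods, function(n) vrm(bathy, n)),
      sprintf("vrm_%d", vrm_neighborhoods)
    )
  )
  env_stack(layers)
}
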
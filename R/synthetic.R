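# Synthetic seascapes with known niches.
#
# Emulates the statistical structure of the study system: seamount-studded
# abyssal bathymetry on a ~1 km geographic grid, environmental fields that
# covary with depth plus spatially correlated noise (including a coarse
# depth-layered 3D field), species whose true suitability surface is known,
# and spatially biased survey effort. Every generator is a pure function of
# (configuration, seed).

# spatially correlated noise: white noise smoothed by a separable Gaussian
# kernel (truncated at 3 sigma, edge-renormalized), rescaled to unit sd
smooth_noise <- function(nr, nc, cor_length_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (cor_length_cells > 0) {
    half <- max(1L, ceiling(3 * cor_length_cells))
    k <- stats::dnorm(-half:half, sd = cor_length_cells)
    k <- k / sum(k)
    smooth1d <- function(x) {
      # replicate edges so the kernel window is always complete
      xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
      as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
    }
    z <- apply(z, 2, smooth1d)
    z <- t(apply(z, 1, smooth1d))
  }
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z - mean(z)
}

#' Generate seamount-studded synthetic bathymetry
#'
#' A smooth abyssal plain (spatially correlated noise around a base depth)
#' with `n_seamounts` Gaussian bumps of randomized height, radius,
#' eccentricity and orientation; a fraction are flat-topped (guyot-like).
#' Depths are negative down and clamped into `depth_range`.
#'
#' @param n_rows,n_cols Grid shape.
#' @param origin_lon,origin_lat Center of the NW cell (degrees).
#' @param cell_size Cell size in degrees (study resolution 0.0083).
#' @param n_seamounts Number of seamounts (>= 0).
#' @param depth_range Two depths (m, negative down), plain floor to
#'   shallowest allowed summit.
#' @param seamount_radius_km Range of seamount radii (km); the default keeps
#'   seamounts small relative to the seascape, as in abyssal study regions
#'   where large terrain features cover a few percent of the area.
#' @param plain_sd SD of the plain's roughness (m).
#' @param plain_cor_cells Correlation length of plain roughness (cells).
#' @param seed Integer seed.
#' @return A bathymetry `bgrid` (m, negative down).
#' @export
make_bathymetry <- function(n_rows = 120, n_cols = 120,
                            origin_lon = -85, origin_lat = -23,
                            cell_size = 0.0083,
                            n_seamounts = 6,
                            depth_range = c(-4500, -1200),
                            seamount_radius_km = c(3, 8),
                            plain_sd = 60, plain_cor_cells = 4,
                            seed = 1L) {
  stopifnot(n_seamounts >= 0)
  if (depth_range[1] >= depth_range[2] || depth_range[2] > 0) {
    stop("depth_range must be increasing and negative (deep, shallow)")
  }
  set.seed(seed)
  base_depth <- depth_range[1] + 0.15 * (depth_range[2] - depth_range[1])
  z <- base_depth + plain_sd * smooth_noise(n_rows, n_cols, plain_cor_cells)
  lon <- matrix(rep(origin_lon + (seq_len(n_cols) - 1) * cell_size, each = n_rows),
                n_rows, n_cols)
  lat <- matrix(rep(origin_lat - (seq_len(n_rows) - 1) * cell_size, times = n_cols),
                n_rows, n_cols)
  if (n_seamounts > 0) {
    span_lon <- (n_cols - 1) * cell_size
    span_lat <- (n_rows - 1) * cell_size
    for (i in seq_len(n_seamounts)) {
      c_lon <- origin_lon + stats::runif(1, 0.15, 0.85) * span_lon
      c_lat <- origin_lat - stats::runif(1, 0.15, 0.85) * span_lat
      height <- stats::runif(1, 0.5, 1.0) * (depth_range[2] - base_depth)
      radius_km <- stats::runif(1, seamount_radius_km[1], seamount_radius_km[2])
      ecc <- stats::runif(1, 1, 2)
      theta <- stats::runif(1, 0, pi)
      guyot <- stats::runif(1) < 0.3
      dx <- (lon - c_lon) * KM_PER_DEGREE * cos(c_lat * pi / 180)
      dy <- (lat - c_lat) * KM_PER_DEGREE
      u <- cos(theta) * dx + sin(theta) * dy
      v <- -sin(theta) * dx + cos(theta) * dy
      q <- (u / radius_km)^2 + (v / (radius_km / ecc))^2
      bump <- height * exp(-q / 2)
      if (guyot) bump <- pmin(bump, 0.85 * height)  # flat summit
      z <- z + bump
    }
  }
  z <- pmin(pmax(z, depth_range[1]), depth_range[2])
  bgrid(z, origin_lon, origin_lat, cell_size, name = "bathymetry")
}

default_field_specs <- function() {
  # depth-covarying nutrients/oxygen in the style of climatological fields;
  # noise levels chosen so the layers correlate only moderately with each
  # other (|r| well below the 0.7 screening threshold), as in a final
  # post-screening predictor set
  list(
    silicate = list(profile = "linear", par = c(a = 5, b = 0.03),
                    noise_sd = 3, cor_length_cells = 6),
    dissolved_oxygen = list(profile = "linear", par = c(a = 6.5, b = -0.0009),
                            noise_sd = 0.9, cor_length_cells = 6),
    poc_flux = list(profile = "exponential", par = c(v0 = 20, k = 0.0008),
                    noise_sd = 1.6, cor_length_cells = 6),
    omega_aragonite = list(profile = "linear", par = c(a = 2.6, b = -0.00045),
                           noise_sd = 0.35, cor_length_cells = 6)
  )
}

profile_fun <- function(spec) {
  switch(
    spec$profile,
    linear = function(d) spec$par[["a"]] + spec$par[["b"]] * d,
    exponential = function(d) spec$par[["v0"]] * exp(-spec$par[["k"]] * d),
    gaussian = function(d) {
      spec$par[["scale"]] * exp(-0.5 * ((d - spec$par[["mu"]]) / spec$par[["sd"]])^2)
    },
    stop("unknown depth profile form: ", spec$profile)
  )
}

#' Generate environmental layers that covary with depth
#'
#' For each field spec, a flat layer v(cell) = f(depth at cell) + spatially
#' correlated noise, plus a coarse depth-layered 3D field whose levels carry
#' f(level depth) plus a depth-independent horizontal noise surface — so its
#' exact seafloor evaluation is known for upscaling tests.
#'
#' @param bathy Bathymetry `bgrid`.
#' @param field_specs Named list of specs: `profile` ("linear",
#'   "exponential", "gaussian"), `par` (named parameters), `noise_sd`,
#'   `cor_length_cells`. Defaults emulate silicate, dissolved oxygen, POC
#'   flux and aragonite saturation.
#' @param layered_var Which spec also becomes the 3D `layered_field`.
#' @param depth_levels Depth levels (m) of the 3D field.
#' @param coarse_factor Coarsening factor of the 3D field's horizontal grid.
#' @param seed Integer seed.
#' @return A list: `stack` (env_stack of flat layers), `field`
#'   (`layered_field`), `specs`.
#' @export
make_env_fields <- function(bathy, field_specs = default_field_specs(),
                            layered_var = names(field_specs)[1],
                            depth_levels = seq(0, 6000, by = 500),
                            coarse_factor = 10, seed = 1L) {
  set.seed(seed)
  depth <- -bathy$values
  nr <- nrow(depth); nc <- ncol(depth)
  layers <- list()
  for (nm in names(field_specs)) {
    spec <- field_specs[[nm]]
    f <- profile_fun(spec)
    vals <- f(depth)
    if (spec$noise_sd > 0) {
      vals <- vals + spec$noise_sd * smooth_noise(nr, nc, spec$cor_length_cells)
    }
    layers[[nm]] <- grid_like(bathy, vals, name = nm)
  }
  # coarse 3D field for the layered variable: levels follow the profile,
  # plus one horizontal noise field shared by all levels
  spec <- field_specs[[layered_var]]
  f <- profile_fun(spec)
  # coarse centers must bracket every fine center for bilinear support
  cnr <- max(2L, ceiling((nr - 1) / coarse_factor) + 1L)
  cnc <- max(2L, ceiling((nc - 1) / coarse_factor) + 1L)
  ccell <- bathy$cell_size * coarse_factor
  hnoise <- if (spec$noise_sd > 0) {
    spec$noise_sd * smooth_noise(cnr, cnc, 1)
  } else {
    matrix(0, cnr, cnc)
  }
  arr <- array(NA_real_, c(length(depth_levels), cnr, cnc))
  for (l in seq_along(depth_levels)) {
    arr[l, , ] <- f(depth_levels[l]) + hnoise
  }
  # coarse grid centered so it covers the fine extent with margin
  fld <- layered_field(
    arr, depth_levels,
    origin_lon = bathy$origin_lon, origin_lat = bathy$origin_lat,
    cell_size = ccell, name = layered_var
  )
  list(stack = env_stack(layers), field = fld, specs = field_specs)
}

response_fun <- function(spec) {
  switch(
    spec$form,
    gaussian = function(x) exp(-0.5 * ((x - spec$mu) / spec$sd)^2),
    logistic = function(x) stats::plogis(spec$k * (x - spec$x0)),
    `threshold-linear` = function(x) {
      pmin(pmax((x - spec$lo) / (spec$hi - spec$lo), 0), 1)
    },
    stop("unknown response form: ", spec$form)
  )
}

#' Simulate a species with a known niche under biased survey effort
#'
#' The true suitability surface is the product of per-variable response
#' functions (rescaled to max 1); presences are a thinned point process —
#' candidate cells drawn proportional to survey effort, accepted with
#' probability equal to suitability — capped to exactly `n_presence`
#' records. The returned truth object carries everything a recovery test
#' needs.
#'
#' @param stack An `env_stack` of predictor layers.
#' @param response_spec Named list (by layer name) of response specs:
#'   `form` "gaussian" (`mu`, `sd`), "logistic" (`x0`, `k`), or
#'   "threshold-linear" (`lo`, `hi`).
#' @param n_presence Number of presence records (study-scale: a few hundred).
#' @param bias_spec `list(type = "uniform")` or `list(type = "hotspots",
#'   centers = 2-column matrix (lon, lat), sd_deg =, weights =)` mixing
#'   Gaussian effort hotspots over a small uniform floor.
#' @param seed Integer seed.
#' @param taxon Taxon label.
#' @return A list: `occurrences` (presence tibble) and `truth`
#'   (`synthetic_truth`: `true_suitability`, `effort`, `response_spec`,
#'   `stack`, `seed`).
#' @export
simulate_species <- function(stack, response_spec, n_presence = 200,
                             bias_spec = list(type = "uniform"), seed = 1L,
                             taxon = "synthetic_taxon") {
  missing <- setdiff(names(response_spec), names(stack$layers))
  if (length(missing) > 0) stop("response_spec references unknown layer(s): ",
                                paste(missing, collapse = ", "))
  ref <- stack$layers[[1]]
  suit <- matrix(1, nrow(ref$values), ncol(ref$values))
  for (nm in names(response_spec)) {
    f <- response_fun(response_spec[[nm]])
    suit <- suit * f(stack$layers[[nm]]$values)
  }
  mx <- max(suit, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 1e-12) stop("degenerate suitability surface (all ~0)")
  suit <- suit / mx
  true_suit <- grid_like(ref, suit, name = "true_suitability")
  # survey-effort surface
  lons <- grid_lons(ref); lats <- grid_lats(ref)
  eff <- matrix(1, nrow(ref$values), ncol(ref$values))
  if (identical(bias_spec$type, "hotspots")) {
    centers <- bias_spec$centers
    wts <- if (is.null(bias_spec$weights)) rep(1, nrow(centers)) else bias_spec$weights
    sd_deg <- bias_spec$sd_deg
    eff <- 0.05 * eff  # uniform floor so no cell has zero effort
    for (i in seq_len(nrow(centers))) {
      kx <- exp(-0.5 * ((lons - centers[i, 1]) / sd_deg)^2)
      ky <- exp(-0.5 * ((lats - centers[i, 2]) / sd_deg)^2)
      eff <- eff + wts[i] * (ky %o% kx)
    }
  }
  eff[is.na(suit)] <- NA_real_
  eff <- eff / sum(eff, na.rm = TRUE)
  effort <- grid_like(ref, eff, name = "effort_truth")
  # thinned point process capped at n_presence
  set.seed(seed)
  pe <- as.vector(eff)
  pe[is.na(pe)] <- 0
  sv <- as.vector(suit)
  accepted <- integer(0)
  tries <- 0
  while (length(accepted) < n_presence && tries < 1000) {
    m <- (n_presence - length(accepted)) * 4 + 20
    cand <- sample.int(length(pe), m, replace = TRUE, prob = pe)
    keep <- stats::runif(m) < sv[cand]
    accepted <- c(accepted, cand[keep])
    tries <- tries + 1
  }
  if (length(accepted) < n_presence) {
    stop("could not draw enough presences; suitability x effort too small")
  }
  accepted <- accepted[seq_len(n_presence)]
  nr <- nrow(ref$values)
  rows <- ((accepted - 1L) %% nr) + 1L
  cols <- ((accepted - 1L) %/% nr) + 1L
  occ <- new_occurrence_set(
    tibble::tibble(taxon = taxon, lon = lons[cols], lat = lats[rows],
                   kind = "presence"),
    provenance = sprintf("simulate_species(seed=%d)", seed)
  )
  truth <- structure(
    list(
      true_suitability = true_suit, effort = effort,
      response_spec = response_spec, stack = stack, seed = seed
    ),
    class = "synthetic_truth"
  )
  list(occurrences = occ, truth = truth)
}

#' Build geomorphic class masks from synthetic bathymetry
#'
#' Simple classifier for summaries: "seamount" cells sit well above the
#' abyssal plain (TPI over `radius_m` above `tpi_cut`), "plain" cells do not.
#'
#' @param bathy Bathymetry `bgrid`.
#' @param radius_m TPI radius (default 10,000 m).
#' @param tpi_cut Elevation above surroundings defining a seamount (m).
#' @return Named list of 0/1 `bgrid` masks (`seamount`, `plain`).
#' @export
make_geomorph_masks <- function(bathy, radius_m = 10000, tpi_cut = 300) {
  t <- tpi(bathy, radius_m)
  sea <- ifelse(is.na(t$values), NA_real_, as.numeric(t$values > tpi_cut))
  plain <- ifelse(is.na(t$values), NA_real_, as.numeric(t$values <= tpi_cut))
  list(
    seamount = grid_like(bathy, sea, name = "seamount"),
    plain = grid_like(bathy, plain, name = "plain")
  )
}
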
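# Independent brute-force oracles: scalar per-cell loops and generic solvers,
# deliberately written along different computational paths than the package
# implementations they check.

KMDEG <- 111.195

oracle_cell_meters <- function(grid) {
  lats <- grid_lats(grid)
  list(dx = KMDEG * 1000 * grid$cell_size * cos(lats * pi / 180),
       dy = KMDEG * 1000 * grid$cell_size)
}

# per-cell central-difference slope (degrees), scalar loop
oracle_slope <- function(grid) {
  z <- grid$values
  mt <- oracle_cell_meters(grid)
  out <- matrix(NA_real_, nrow(z), ncol(z))
  for (r in 2:(nrow(z) - 1)) {
    for (c in 2:(ncol(z) - 1)) {
      fx <- (z[r, c + 1] - z[r, c - 1]) / (2 * mt$dx[r])
      fy <- (z[r - 1, c] - z[r + 1, c]) / (2 * mt$dy)
      out[r, c] <- atan(sqrt(fx^2 + fy^2)) * 180 / pi
    }
  }
  out
}

oracle_aspect <- function(grid) {
  z <- grid$values
  mt <- oracle_cell_meters(grid)
  east <- matrix(NA_real_, nrow(z), ncol(z)); north <- east
  for (r in 2:(nrow(z) - 1)) {
    for (c in 2:(ncol(z) - 1)) {
      fx <- (z[r, c + 1] - z[r, c - 1]) / (2 * mt$dx[r])
      fy <- (z[r - 1, c] - z[r + 1, c]) / (2 * mt$dy)
      m <- sqrt(fx^2 + fy^2)
      if (m > 0) {
        east[r, c] <- -fx / m
        north[r, c] <- -fy / m
      }
    }
  }
  list(eastness = east, northness = north)
}

# least-squares quadratic surface per 3x3 window via lm(), then curvatures
oracle_curvature <- function(grid) {
  z <- grid$values
  mt <- oracle_cell_meters(grid)
  gen <- matrix(NA_real_, nrow(z), ncol(z)); cross <- gen; longi <- gen
  for (r in 2:(nrow(z) - 1)) {
    for (c in 2:(ncol(z) - 1)) {
      gx <- mt$dx[r]; gy <- mt$dy
      pts <- expand.grid(i = -1:1, j = -1:1)
      df <- data.frame(
        z = z[cbind(r + pts$i, c + pts$j)],
        x = pts$j * gx, y = -pts$i * gy
      )
      fit <- stats::lm(z ~ I(x^2) + I(y^2) + I(x * y) + x + y, data = df)
      cf <- stats::coef(fit)
      a <- cf[["I(x^2)"]]; b <- cf[["I(y^2)"]]; cc <- cf[["I(x * y)"]]
      d <- cf[["x"]]; e <- cf[["y"]]
      g2 <- d^2 + e^2
      gen[r, c] <- -2 * (a + b)
      if (g2 < 1e-24) {
        longi[r, c] <- gen[r, c] / 2
        cross[r, c] <- gen[r, c] / 2
      } else {
        longi[r, c] <- -2 * (a * d^2 + cc * d * e + b * e^2) / g2
        cross[r, c] <- -2 * (a * e^2 - cc * d * e + b * d^2) / g2
      }
    }
  }
  list(general = gen, cross_sectional = cross, longitudinal = longi)
}

# triangle area from side lengths (Heron), avoiding the cross-product path
heron <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p2)^2)); b <- sqrt(sum((p2 - p3)^2)); c <- sqrt(sum((p3 - p1)^2))
  s <- (a + b + c) / 2
  sqrt(max(s * (s - a) * (s - b) * (s - c), 0))
}

oracle_roughness <- function(grid) {
  z <- grid$values
  mt <- oracle_cell_meters(grid)
  out <- matrix(NA_real_, nrow(z), ncol(z))
  dirs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  for (r in 2:(nrow(z) - 1)) {
    for (c in 2:(ncol(z) - 1)) {
      dx <- mt$dx[r]; dy <- mt$dy
      center <- c(0, 0, z[r, c])
      mids <- lapply(dirs, function(d) {
        c(d[2] * dx / 2, -d[1] * dy / 2, (z[r, c] + z[r + d[1], c + d[2]]) / 2)
      })
      area <- 0
      for (k in 1:8) {
        area <- area + heron(center, mids[[k]], mids[[if (k == 8) 1 else k + 1]])
      }
      out[r, c] <- area / (dx * dy)
    }
  }
  out
}

oracle_tpi <- function(grid, radius_m) {
  z <- grid$values
  mt <- oracle_cell_meters(grid)
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- c(); complete <- TRUE
      for (rr in seq_len(nr)) {
        for (cc in seq_len(nc)) {
          if (rr == r && cc == c) next
          dist <- sqrt(((rr - r) * mt$dy)^2 + ((cc - c) * mt$dx[r])^2)
          if (dist <= radius_m) vals <- c(vals, z[rr, cc])
        }
      }
      # completeness: would any in-radius offset fall off the grid?
      max_dr <- floor(radius_m / mt$dy); max_dc <- floor(radius_m / mt$dx[r])
      for (dr in -max_dr:max_dr) for (dc in -max_dc:max_dc) {
        if (dr == 0 && dc == 0) next
        if ((dr * mt$dy)^2 + (dc * mt$dx[r])^2 <= radius_m^2) {
          if (r + dr < 1 || r + dr > nr || c + dc < 1 || c + dc > nc) complete <- FALSE
        }
      }
      if (complete && length(vals) > 0 && !anyNA(vals) && !is.na(z[r, c])) {
        out[r, c] <- z[r, c] - mean(vals)
      }
    }
  }
  out
}

oracle_vrm <- function(grid, n) {
  z <- grid$values
  mt <- oracle_cell_meters(grid)
  nr <- nrow(z); nc <- ncol(z)
  nx <- matrix(NA_real_, nr, nc); ny <- nx; nz <- nx
  for (r in 2:(nr - 1)) {
    for (c in 2:(nc - 1)) {
      fx <- (z[r, c + 1] - z[r, c - 1]) / (2 * mt$dx[r])
      fy <- (z[r - 1, c] - z[r + 1, c]) / (2 * mt$dy)
      sl <- atan(sqrt(fx^2 + fy^2))
      m <- sqrt(fx^2 + fy^2)
      if (m > 0) {
        nx[r, c] <- sin(sl) * (-fx / m); ny[r, c] <- sin(sl) * (-fy / m)
      } else {
        nx[r, c] <- 0; ny[r, c] <- 0
      }
      nz[r, c] <- cos(sl)
    }
  }
  h <- (n - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (r - h < 1 || r + h > nr || c - h < 1 || c + h > nc) next
      sx <- 0; sy <- 0; sz <- 0; ok <- TRUE
      for (rr in (r - h):(r + h)) for (cc in (c - h):(c + h)) {
        if (is.na(nz[rr, cc])) { ok <- FALSE } else {
          sx <- sx + nx[rr, cc]; sy <- sy + ny[rr, cc]; sz <- sz + nz[rr, cc]
        }
      }
      if (ok) out[r, c] <- 1 - sqrt(sx^2 + sy^2 + sz^2) / n^2
    }
  }
  out
}

# double-loop Gaussian kernel sum over cells and points
oracle_kde <- function(pts_lon, pts_lat, grid, hx, hy) {
  lons <- grid_lons(grid); lats <- grid_lats(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  dens <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      s <- 0
      for (i in seq_along(pts_lon)) {
        s <- s + exp(-0.5 * ((lons[c] - pts_lon[i]) / hx)^2) *
          exp(-0.5 * ((lats[r] - pts_lat[i]) / hy)^2)
      }
      dens[r, c] <- s
    }
  }
  dens[is.na(grid$values)] <- NA
  dens / sum(dens, na.rm = TRUE)
}

# exhaustive pairwise AUC
oracle_auc <- function(pres, bg) {
  s <- 0
  for (p in pres) for (b in bg) {
    s <- s + if (p > b) 1 else if (p == b) 0.5 else 0
  }
  s / (length(pres) * length(bg))
}

# exhaustive threshold scan for max TSS over a fine grid of candidates
oracle_tss_max <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  cand <- c(cand - 1e-9, cand + 1e-9, min(cand) - 1)
  max(vapply(cand, function(t) {
    mean(pres >= t) + mean(bg < t) - 1
  }, numeric(1)))
}

# small random bathymetry-like grid, near the equator so geometry is benign
random_grid <- function(nr, nc, seed, cell = 0.01, origin_lat = 0.05,
                        scale = 100, base = -3000) {
  set.seed(seed)
  bgrid(base + scale * matrix(stats::rnorm(nr * nc), nr, nc),
        origin_lon = -10, origin_lat = origin_lat, cell_size = cell,
        name = "bathy")
}
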
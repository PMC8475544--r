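# Aligned predictor stacks, seafloor upscaling of depth-layered fields,
# correlation screening, and point-based validation.

#' Bundle aligned grids into a named predictor stack
#'
#' @param layers Named list of `bgrid` objects sharing origin, cell size and
#'   shape.
#' @return An `env_stack`.
#' @export
env_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == "") || anyDuplicated(names(layers))) {
    stop("env_stack layers must have unique non-empty names")
  }
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "bgrid")) stop("layer '", nm, "' is not a bgrid")
    if (!same_geometry(layers[[nm]], ref)) {
      stop("layer '", nm, "' is not aligned with layer '", names(layers)[1], "'")
    }
  }
  structure(list(layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf(
    "<env_stack> %d layers on %d x %d grid: %s\n",
    length(x$layers), nrow(ref$values), ncol(ref$values),
    paste(names(x$layers), collapse = ", ")
  ))
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

#' Tabulate a stack as one row per jointly unmasked cell
#'
#' @param x An `env_stack`.
#' @param drop_na Keep only cells unmasked in every layer (default TRUE).
#' @param ... Unused.
#' @return A tibble with `lon`, `lat`, `row`, `col` and one column per layer.
#' @export
as_tibble.env_stack <- function(x, drop_na = TRUE, ...) {
  ref <- x$layers[[1]]
  out <- as_tibble.bgrid(ref, drop_na = FALSE)
  out$value <- NULL
  for (nm in names(x$layers)) out[[nm]] <- as.vector(x$layers[[nm]]$values)
  if (drop_na) {
    keep <- stats::complete.cases(out[, names(x$layers), drop = FALSE])
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Extract stack values at point locations
#'
#' @param stack An `env_stack`.
#' @param lon,lat Coordinates.
#' @return A tibble with one column per layer; NA where outside or masked.
#' @export
extract_stack <- function(stack, lon, lat) {
  ref <- stack$layers[[1]]
  idx <- cell_index(ref, lon, lat)
  out <- tibble::tibble(.rows = length(lon))
  inside <- !is.na(idx$row)
  for (nm in names(stack$layers)) {
    v <- rep(NA_real_, length(lon))
    v[inside] <- stack$layers[[nm]]$values[cbind(idx$row[inside], idx$col[inside])]
    out[[nm]] <- v
  }
  out
}

# ---- depth-layered 3D fields -------------------------------------------------

#' A coarse 3D field on depth levels
#'
#' @param values 3D array `[depth_level, row, col]`, row 1 northernmost.
#' @param depth_levels Strictly increasing depths (m, positive down), >= 2.
#' @param origin_lon,origin_lat Center of the NW cell of the coarse grid.
#' @param cell_size Coarse cell size (degrees).
#' @param name Field label.
#' @return A `layered_field`.
#' @export
layered_field <- function(values, depth_levels, origin_lon, origin_lat, cell_size,
                          name = "field") {
  stopifnot(length(dim(values)) == 3, dim(values)[1] == length(depth_levels))
  if (length(depth_levels) < 2 || any(diff(depth_levels) <= 0)) {
    stop("depth_levels must be strictly increasing with at least 2 levels")
  }
  structure(
    list(
      values = values, depth_levels = as.numeric(depth_levels),
      origin_lon = origin_lon, origin_lat = origin_lat,
      cell_size = cell_size, name = name
    ),
    class = "layered_field"
  )
}

# one coarse horizontal level as a bgrid
field_level <- function(field, l) {
  bgrid(
    field$values[l, , , drop = TRUE],
    field$origin_lon, field$origin_lat, field$cell_size,
    name = sprintf("%s_z%g", field$name, field$depth_levels[l])
  )
}

#' Write/read a layered field as a plain-text file
#'
#' Simple text serialization: a header line `nlev nrow ncol origin_lon
#' origin_lat cell_size`, a line of depth levels, then `nlev` blocks of
#' `nrow` lines of `ncol` values (north row first).
#'
#' @param field A `layered_field`.
#' @param path File path.
#' @return `write_layered_field` returns `path` invisibly; `read_layered_field`
#'   a `layered_field`.
#' @export
write_layered_field <- function(field, path) {
  d <- dim(field$values)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(sprintf(
    "%d %d %d %.10f %.10f %.12g", d[1], d[2], d[3],
    field$origin_lon, field$origin_lat, field$cell_size
  ), con)
  writeLines(paste(sprintf("%.9g", field$depth_levels), collapse = " "), con)
  for (l in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      writeLines(paste(sprintf("%.9g", field$values[l, r, ]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_layered_field
#' @export
read_layered_field <- function(path) {
  hdr <- scan(path, what = double(), nlines = 1, quiet = TRUE)
  levels <- scan(path, what = double(), skip = 1, nlines = 1, quiet = TRUE)
  nlev <- as.integer(hdr[1]); nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
  body <- scan(path, what = double(), skip = 2, quiet = TRUE)
  arr <- array(NA_real_, c(nlev, nr, nc))
  i <- 1
  for (l in seq_len(nlev)) for (r in seq_len(nr)) {
    arr[l, r, ] <- body[i:(i + nc - 1)]
    i <- i + nc
  }
  layered_field(arr, levels, hdr[4], hdr[5], hdr[6],
                name = sub("\\.[^.]*$", "", basename(path)))
}

#' Upscale a depth-layered field to the seafloor
#'
#' Approximates near-bottom conditions on a fine bathymetry grid: for each
#' fine cell, every depth level of the coarse field is interpolated
#' horizontally (bilinear) to the cell center, then the vertical profile is
#' interpolated linearly to the cell's bathymetric depth. Depths above the
#' first level or below the deepest level clamp to the end levels. Fine cells
#' outside the coarse field's bilinear support are nodata.
#'
#' @param field A `layered_field`.
#' @param bathy Fine bathymetry `bgrid` (m, negative down).
#' @return A `bgrid` on the bathymetry geometry.
#' @export
upscale_to_seafloor <- function(field, bathy) {
  nlev <- length(field$depth_levels)
  # horizontal pass: each level resampled onto the fine geometry
  horiz <- lapply(seq_len(nlev), function(l) {
    align_and_resample(field_level(field, l), bathy, method = "bilinear")$values
  })
  depth <- -bathy$values  # positive down
  lv <- field$depth_levels
  out <- matrix(NA_real_, nrow(depth), ncol(depth))
  d_cl <- pmin(pmax(depth, lv[1]), lv[nlev])
  # bracketing level below each depth
  bin <- findInterval(d_cl, lv, all.inside = TRUE)
  for (l in seq_len(nlev - 1)) {
    sel <- which(bin == l & !is.na(d_cl))
    if (length(sel) == 0) next
    t <- (d_cl[sel] - lv[l]) / (lv[l + 1] - lv[l])
    out[sel] <- (1 - t) * horiz[[l]][sel] + t * horiz[[l + 1]][sel]
  }
  out[is.na(depth)] <- NA_real_
  grid_like(bathy, out, name = field$name)
}

# ---- correlation screening ---------------------------------------------------

#' Pearson correlation matrix among stack layers
#'
#' Computed over jointly unmasked cells (complete cases), optionally on a
#' seeded random subsample for large grids.
#'
#' @param stack An `env_stack` with >= 2 layers.
#' @param n_sample Optional number of cells to subsample.
#' @param seed Seed for the subsample.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(stack, n_sample = NULL, seed = 1L) {
  if (length(stack$layers) < 2) stop("need at least 2 layers to correlate")
  tab <- as_tibble.env_stack(stack)[, names(stack$layers), drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 jointly unmasked cells")
  if (!is.null(n_sample) && n_sample < nrow(tab)) {
    set.seed(seed)
    tab <- tab[sample.int(nrow(tab), n_sample), , drop = FALSE]
  }
  stats::cor(as.matrix(tab), method = "pearson")
}

#' Hierarchical clustering of variables by correlation
#'
#' Agglomerative clustering (average linkage) on distance 1 - |r|: variables
#' carrying similar information merge low in the tree.
#'
#' @param corr Symmetric correlation matrix.
#' @return An `hclust` tree.
#' @export
cluster_variables <- function(corr) {
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("correlation matrix must be symmetric")
  d <- stats::as.dist(1 - abs(corr))
  stats::hclust(d, method = "average")
}

#' Greedy correlation screen over a priority ordering
#'
#' Walks `keep_priority` in order, keeping each variable unless its absolute
#' correlation with an already-kept variable exceeds `threshold`. Expert
#' preference (e.g. biological relevance) enters only through the ordering.
#'
#' @param corr Correlation matrix with dimnames.
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.7.
#' @param keep_priority Character vector ordering all variables.
#' @return A list: `kept` (names), `dropped` (names), `flagged_pairs`
#'   (tibble of all super-threshold pairs with their r).
#' @export
screen_variables <- function(corr, threshold = 0.7, keep_priority = rownames(corr)) {
  vars <- rownames(corr)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (!setequal(keep_priority, vars) || length(keep_priority) != length(vars)) {
    stop("keep_priority must order exactly the variables of corr")
  }
  kept <- character()
  for (v in keep_priority) {
    if (length(kept) == 0 || all(abs(corr[v, kept]) <= threshold)) {
      kept <- c(kept, v)
    }
  }
  pr <- which(abs(corr) > threshold & upper.tri(corr), arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = vars[pr[, 1]], var2 = vars[pr[, 2]],
    r = corr[pr]
  )
  list(kept = kept, dropped = setdiff(vars, kept), flagged_pairs = flagged)
}

#' Validate an upscaled grid against near-bottom point samples
#'
#' Mirrors validation against quality-controlled bottle casts: samples taken
#' within `near_bottom_tolerance_m` of the bottom are paired with the grid
#' value at their cell and correlated.
#'
#' @param grid A `bgrid`.
#' @param samples Tibble/data frame with columns `lon`, `lat`,
#'   `sample_depth_m`, `bottom_depth_m`, `value`.
#' @param near_bottom_tolerance_m Max height above bottom (m), default 50.
#' @return A list: `r` (Pearson, NA if < 3 pairs), `n`, `pairs` (tibble of
#'   observed vs grid values). Empty input yields `n = 0`, not an error.
#' @export
validate_against_points <- function(grid, samples, near_bottom_tolerance_m = 50) {
  stopifnot(near_bottom_tolerance_m > 0)
  samples <- tibble::as_tibble(samples)
  keep <- (samples$bottom_depth_m - samples$sample_depth_m) <= near_bottom_tolerance_m &
    samples$bottom_depth_m >= samples$sample_depth_m
  near <- samples[which(keep), , drop = FALSE]
  if (nrow(near) == 0) {
    return(list(r = NA_real_, n = 0L,
                pairs = tibble::tibble(observed = double(), predicted = double())))
  }
  idx <- cell_index(grid, near$lon, near$lat)
  gv <- rep(NA_real_, nrow(near))
  inside <- !is.na(idx$row)
  gv[inside] <- grid$values[cbind(idx$row[inside], idx$col[inside])]
  ok <- !is.na(gv)
  pairs <- tibble::tibble(observed = near$value[ok], predicted = gv[ok])
  r <- if (nrow(pairs) >= 3) stats::cor(pairs$observed, pairs$predicted) else NA_real_
  list(r = r, n = nrow(pairs), pairs = pairs)
}
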
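# Geographic raster container and I/O.
#
# A `bgrid` is a matrix of cell values on an unprojected (longitude/latitude)
# grid, indexed row-major from the north-west corner: row 1 is the
# northernmost row, column 1 the westernmost column. `origin_lon`/`origin_lat`
# are the coordinates of the CENTER of cell [1, 1]; `cell_size` is the cell
# edge in degrees (square cells). Nodata cells are NA. Values are stored in
# double precision; file round-trips promise single-precision fidelity.

KM_PER_DEGREE <- 111.195  # 2*pi*6371.0 km / 360

#' Construct a geographic grid
#'
#' @param values Numeric matrix, row 1 = northernmost row. NA marks nodata.
#' @param origin_lon,origin_lat Coordinates (degrees) of the center of the
#'   north-west cell `[1, 1]`.
#' @param cell_size Cell edge in degrees (> 0); square cells.
#' @param name Layer label.
#' @return A `bgrid` object.
#' @export
bgrid <- function(values, origin_lon, origin_lat, cell_size, name = "layer") {
  values <- as.matrix(values)
  stopifnot(nrow(values) > 0, ncol(values) > 0, cell_size > 0)
  if (any(is.infinite(values))) {
    stop("grid values must be finite or NA")
  }
  structure(
    list(
      values = values,
      origin_lon = as.numeric(origin_lon),
      origin_lat = as.numeric(origin_lat),
      cell_size = as.numeric(cell_size),
      name = as.character(name)
    ),
    class = "bgrid"
  )
}

#' @export
print.bgrid <- function(x, ...) {
  cat(sprintf(
    "<bgrid '%s'> %d x %d cells, %.6g deg/cell, NW center (%.5f, %.5f), %d nodata\n",
    x$name, nrow(x$values), ncol(x$values), x$cell_size,
    x$origin_lon, x$origin_lat, sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.bgrid <- function(x) dim(x$values)

#' Longitudes of cell centers (by column) and latitudes (by row)
#' @param grid A `bgrid`.
#' @return Numeric vector of center coordinates.
#' @export
grid_lons <- function(grid) grid$origin_lon + (seq_len(ncol(grid$values)) - 1) * grid$cell_size

#' @rdname grid_lons
#' @export
grid_lats <- function(grid) grid$origin_lat - (seq_len(nrow(grid$values)) - 1) * grid$cell_size

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Copy a grid's geometry with new values
#' @param grid Template `bgrid`.
#' @param values Replacement matrix (same shape).
#' @param name Optional new label.
#' @return A `bgrid`.
#' @export
grid_like <- function(grid, values, name = grid$name) {
  stopifnot(all(dim(values) == dim(grid$values)))
  bgrid(values, grid$origin_lon, grid$origin_lat, grid$cell_size, name)
}

#' Tabulate a grid as (lon, lat, value) rows
#'
#' Unmasked cells only by default; ordered row-major from the north-west.
#'
#' @param x A `bgrid`.
#' @param drop_na Drop nodata cells (default TRUE).
#' @param ... Unused.
#' @return A tibble with columns `lon`, `lat`, `row`, `col`, `value`.
#' @export
as_tibble.bgrid <- function(x, drop_na = TRUE, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    lon = rep(grid_lons(x), each = nr),
    lat = rep(grid_lats(x), times = nc),
    value = as.vector(x$values)
  )
  if (drop_na) out <- out[!is.na(out$value), , drop = FALSE]
  out[, c("lon", "lat", "row", "col", "value")]
}

#' Row/column indices of the cell containing a point
#'
#' Points outside the grid get NA indices.
#'
#' @param grid A `bgrid`.
#' @param lon,lat Point coordinates (degrees).
#' @return A list with integer vectors `row` and `col`.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- as.integer(round((lon - grid$origin_lon) / grid$cell_size)) + 1L
  row <- as.integer(round((grid$origin_lat - lat) / grid$cell_size)) + 1L
  bad <- col < 1L | col > ncol(grid$values) | row < 1L | row > nrow(grid$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' The plain-text `.asc` raster standard: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the northernmost row down. Cells equal to the nodata value are masked
#' (NA).
#'
#' @param path File path.
#' @param format Only `"asc"` (ESRI ASCII grid) is supported.
#' @param name Layer label; defaults to the file stem.
#' @return A `bgrid`.
#' @export
read_grid <- function(path, format = c("asc"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header incomplete in ", path, " (multi-band or foreign format?)")
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  bgrid(
    m,
    origin_lon = hdr$xllcorner + hdr$cellsize / 2,
    origin_lat = hdr$yllcorner + (nr - 0.5) * hdr$cellsize,
    cell_size = hdr$cellsize,
    name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name
  )
}

#' Write a grid to an ESRI ASCII grid file
#'
#' Values are written with 9 significant digits (single-precision fidelity);
#' nodata cells are written as -9999 (or a grid-safe alternative).
#'
#' @param grid A `bgrid`.
#' @param path Destination path.
#' @param nodata Numeric sentinel for masked cells.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "bgrid"))
  if (any(!is.na(grid$values) & grid$values == nodata)) {
    nodata <- min(grid$values, na.rm = TRUE) - 1e6
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  con <- tryCatch(file(path, open = "wt"), error = function(e) {
    stop("cannot write raster to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", grid$origin_lon - grid$cell_size / 2),
    sprintf("yllcorner %.10f", grid$origin_lat - (nr - 0.5) * grid$cell_size),
    sprintf("cellsize %.12g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m <- grid$values
  m[is.na(m)] <- nodata
  for (r in seq_len(nr)) {
    writeLines(paste(sprintf("%.9g", m[r, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Align a source grid onto a template's geometry
#'
#' Resamples `source` so the output shares the template's origin, cell size
#' and shape. `"nearest"` copies the value of the enclosing source cell (no
#' interpolation); `"bilinear"` interpolates from the four surrounding source
#' cell centers, masking wherever any contributor is masked.
#'
#' @param source,template `bgrid` objects with overlapping extents.
#' @param method `"nearest"` or `"bilinear"`.
#' @return A `bgrid` on the template geometry carrying the source's values.
#' @export
align_and_resample <- function(source, template, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (same_geometry(source, template)) {
    return(grid_like(template, source$values, name = source$name))
  }
  lons <- grid_lons(template); lats <- grid_lats(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  # fractional source index of each template cell center
  fx <- (rep(lons, each = nr) - source$origin_lon) / source$cell_size + 1
  fy <- (source$origin_lat - rep(lats, times = nc)) / source$cell_size + 1
  snr <- nrow(source$values); snc <- ncol(source$values)
  out <- rep(NA_real_, nr * nc)
  if (method == "nearest") {
    # round the zero-based offset (not offset + 1) so half-cell ties break
    # the same way as cell_index()
    ci <- as.integer(round(fx - 1)) + 1L; ri <- as.integer(round(fy - 1)) + 1L
    ok <- ci >= 1L & ci <= snc & ri >= 1L & ri <= snr
    out[ok] <- source$values[cbind(ri[ok], ci[ok])]
  } else {
    c0 <- floor(fx); r0 <- floor(fy)
    tx <- fx - c0; ty <- fy - r0
    # clamp so template centers between the edge cell center and the grid edge
    # still interpolate (degenerate weight on the edge cell)
    at_edge_x <- fx >= 1 & fx <= snc; at_edge_y <- fy >= 1 & fy <= snr
    c0[c0 < 1] <- 1; c0[c0 > snc - 1] <- snc - 1
    r0[r0 < 1] <- 1; r0[r0 > snr - 1] <- snr - 1
    tx <- fx - c0; ty <- fy - r0
    ok <- at_edge_x & at_edge_y
    idx <- which(ok)
    v00 <- source$values[cbind(r0[idx], c0[idx])]
    v01 <- source$values[cbind(r0[idx], c0[idx] + 1L)]
    v10 <- source$values[cbind(r0[idx] + 1L, c0[idx])]
    v11 <- source$values[cbind(r0[idx] + 1L, c0[idx] + 1L)]
    out[idx] <- (1 - ty[idx]) * ((1 - tx[idx]) * v00 + tx[idx] * v01) +
      ty[idx] * ((1 - tx[idx]) * v10 + tx[idx] * v11)
  }
  if (all(is.na(out))) {
    stop("source and template extents do not overlap")
  }
  grid_like(template, matrix(out, nrow = nr, ncol = nc), name = source$name)
}

#' Per-cell area in square kilometers
#'
#' Spherical approximation on the geographic grid: a cell at latitude phi has
#' area (cell_size * 111.195 km)^2 * cos(phi), shrinking toward the poles.
#'
#' @param grid A `bgrid`.
#' @return A `bgrid` of areas (km^2), unmasked.
#' @export
cell_area_km2 <- function(grid) {
  lats <- grid_lats(grid)
  row_area <- (grid$cell_size * KM_PER_DEGREE)^2 * cos(lats * pi / 180)
  m <- matrix(row_area, nrow = nrow(grid$values), ncol = ncol(grid$values))
  grid_like(grid, m, name = "cell_area_km2")
}
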
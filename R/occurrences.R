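# Occurrence ingestion, the kernel-density survey-effort surface, bias-matched
# pseudoabsence sampling, and design-matrix assembly.
#
# Occurrence sets are tibbles with columns `taxon`, `lon`, `lat`, `kind`
# ("presence" or "pseudoabsence") plus a `provenance` attribute; they pipe
# directly into dplyr.

new_occurrence_set <- function(df, provenance = "unknown") {
  out <- tibble::as_tibble(df)
  attr(out, "provenance") <- provenance
  out
}

#' Load presence records from a table, dropping duplicates and strays
#'
#' Accepts the conventional presence-only export format (columns `taxon`,
#' `longitude`, `latitude`, optional `kind`; `lon`/`lat` also accepted).
#' Exact-coordinate duplicates (same lon, lat, kind) are removed and records
#' outside the grid extent dropped, with counts attached as attributes
#' `n_duplicates` and `n_outside`.
#'
#' @param records Data frame or path to a CSV file.
#' @param grid A `bgrid` defining the study extent.
#' @param provenance Source label.
#' @return An occurrence tibble (`taxon`, `lon`, `lat`, `kind`).
#' @export
load_and_dedup <- function(records, grid, provenance = "csv") {
  if (is.character(records)) {
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  }
  records <- tibble::as_tibble(records)
  nm <- names(records)
  lon_col <- intersect(c("longitude", "lon"), nm)[1]
  lat_col <- intersect(c("latitude", "lat"), nm)[1]
  if (is.na(lon_col) || is.na(lat_col)) stop("records need longitude/latitude columns")
  lon <- suppressWarnings(as.numeric(records[[lon_col]]))
  lat <- suppressWarnings(as.numeric(records[[lat_col]]))
  bad <- is.na(lon) | is.na(lat)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable coordinates skipped")
  }
  if (all(bad)) stop("no parseable records")
  df <- tibble::tibble(
    taxon = if ("taxon" %in% nm) as.character(records$taxon) else "taxon",
    lon = lon, lat = lat,
    kind = if ("kind" %in% nm) as.character(records$kind) else "presence"
  )[!bad, ]
  n0 <- nrow(df)
  df <- dplyr::distinct(df, .data$lon, .data$lat, .data$kind, .keep_all = TRUE)
  n_dup <- n0 - nrow(df)
  half <- grid$cell_size / 2
  inside <- df$lon >= grid$origin_lon - half &
    df$lon <= grid$origin_lon + (ncol(grid$values) - 1) * grid$cell_size + half &
    df$lat <= grid$origin_lat + half &
    df$lat >= grid$origin_lat - (nrow(grid$values) - 1) * grid$cell_size - half
  n_out <- sum(!inside)
  out <- new_occurrence_set(df[inside, , drop = FALSE], provenance)
  attr(out, "n_duplicates") <- n_dup
  attr(out, "n_outside") <- n_out
  out
}

# Scott's normal-reference bandwidth per axis for a 2D KDE
scott_bandwidth <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) s <- 1e-6
  s * n^(-1 / 6)
}

#' Kernel density estimate of survey effort
#'
#' A 2D Gaussian-kernel density of the presence locations, evaluated at every
#' unmasked cell center and normalized to sum to 1 over unmasked cells. Used
#' as a spatial proxy for sampling effort, so pseudoabsences can carry the
#' same sampling bias as the presences.
#'
#' @param presences Occurrence tibble (rows of kind "presence" are used).
#' @param grid A `bgrid` supplying geometry and mask.
#' @param bandwidth `"scott"` for the per-axis normal-reference rule, or a
#'   numeric length-1/2 bandwidth in degrees (lon, lat).
#' @return A `bgrid` of effort probabilities (sums to 1; NA on masked cells).
#' @export
kde_effort_surface <- function(presences, grid, bandwidth = "scott") {
  pts <- presences[presences$kind == "presence", , drop = FALSE]
  if (nrow(pts) < 2) stop("kernel density needs at least 2 presence records")
  if (identical(bandwidth, "scott")) {
    hx <- scott_bandwidth(pts$lon); hy <- scott_bandwidth(pts$lat)
  } else {
    bandwidth <- rep(as.numeric(bandwidth), length.out = 2)
    stopifnot(all(bandwidth > 0))
    hx <- bandwidth[1]; hy <- bandwidth[2]
  }
  lons <- grid_lons(grid); lats <- grid_lats(grid)
  # separable Gaussian kernel: density[r, c] = sum_i ky[i, r] * kx[i, c]
  kx <- outer(pts$lon, lons, function(p, g) exp(-0.5 * ((g - p) / hx)^2))
  ky <- outer(pts$lat, lats, function(p, g) exp(-0.5 * ((g - p) / hy)^2))
  dens <- crossprod(ky, kx)  # nrow x ncol
  dens[is.na(grid$values)] <- NA_real_
  total <- sum(dens, na.rm = TRUE)
  if (total <= 0) stop("degenerate effort surface (all mass on masked cells)")
  out <- grid_like(grid, dens / total, name = "effort")
  attr(out, "bandwidth") <- c(lon = hx, lat = hy)
  out
}

#' Sample bias-matched pseudoabsences from an effort surface
#'
#' Draws `n` cells (with replacement) with probability proportional to the
#' effort density and records them at cell-center coordinates, giving a
#' pseudoabsence set carrying the same spatial sampling bias as the
#' presences. Cells holding presences can be excluded first.
#'
#' @param density Normalized effort `bgrid` (e.g. from
#'   [kde_effort_surface()]).
#' @param n Number of pseudoabsence records (study default 10,000).
#' @param seed Integer seed; draws are reproducible.
#' @param exclude Optional occurrence tibble whose cells get zero probability.
#' @param taxon Taxon label for the output records.
#' @return An occurrence tibble of `n` rows with kind "pseudoabsence".
#' @export
sample_pseudoabsences <- function(density, n = 10000, seed = 1L, exclude = NULL,
                                  taxon = "taxon") {
  stopifnot(n >= 1)
  prob <- density$values
  prob[is.na(prob)] <- 0
  if (!is.null(exclude) && nrow(exclude) > 0) {
    idx <- cell_index(density, exclude$lon, exclude$lat)
    ok <- !is.na(idx$row)
    prob[cbind(idx$row[ok], idx$col[ok])] <- 0
  }
  if (sum(prob) <= 0) stop("all probability mass excluded; cannot sample pseudoabsences")
  set.seed(seed)
  cells <- sample.int(length(prob), size = n, replace = TRUE, prob = as.vector(prob))
  nr <- nrow(prob)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  new_occurrence_set(
    tibble::tibble(
      taxon = taxon,
      lon = grid_lons(density)[cols],
      lat = grid_lats(density)[rows],
      kind = "pseudoabsence"
    ),
    provenance = sprintf("kde_pseudoabsence(seed=%d)", seed)
  )
}

#' Assemble the model design matrix
#'
#' Extracts the predictor stack at every presence and pseudoabsence record,
#' drops rows touching any masked predictor (count attached as attribute
#' `n_masked_dropped`), labels presences `y = 1`, and attaches prevalence
#' weights equalizing total class weight (each class sums to half the total,
#' scaled to mean 1), so a few hundred presences are not swamped by 10,000
#' pseudoabsences.
#'
#' @param presences,pseudoabsences Occurrence tibbles.
#' @param stack An aligned `env_stack` of predictors.
#' @return An `sdm_design` tibble: `lon`, `lat`, `y`, `weight`, then one
#'   column per predictor (names in attribute `predictors`).
#' @export
build_design_matrix <- function(presences, pseudoabsences, stack) {
  if (nrow(presences) == 0 || nrow(pseudoabsences) == 0) {
    stop("both presence and pseudoabsence sets must be non-empty")
  }
  occ <- dplyr::bind_rows(
    dplyr::mutate(presences[, c("lon", "lat")], y = 1),
    dplyr::mutate(pseudoabsences[, c("lon", "lat")], y = 0)
  )
  vals <- extract_stack(stack, occ$lon, occ$lat)
  keep <- stats::complete.cases(vals)
  dm <- dplyr::bind_cols(occ[keep, , drop = FALSE], vals[keep, , drop = FALSE])
  if (nrow(dm) == 0) stop("no records remain after masking")
  if (!any(dm$y == 1) || !any(dm$y == 0)) {
    stop("one class vanished after masking; cannot build a usable design matrix")
  }
  n <- nrow(dm); n1 <- sum(dm$y == 1); n0 <- n - n1
  dm$weight <- ifelse(dm$y == 1, n / (2 * n1), n / (2 * n0))
  dm <- dm[, c("lon", "lat", "y", "weight", names(stack$layers))]
  attr(dm, "predictors") <- names(stack$layers)
  attr(dm, "n_masked_dropped") <- sum(!keep)
  class(dm) <- c("sdm_design", class(dm))
  dm
}

design_predictors <- function(dm) {
  p <- attr(dm, "predictors")
  if (is.null(p)) setdiff(names(dm), c("lon", "lat", "y", "weight")) else p
}

#' Environmental distributions of presences, pseudoabsences and random background
#'
#' The raw per-group value samples and quantiles per variable (bean-plot
#' inputs): how conditions at the occurrences compare with the bias-matched
#' pseudoabsences and with an unbiased random background.
#'
#' @param presences,pseudoabsences Occurrence tibbles.
#' @param stack An `env_stack`.
#' @param n_random Number of random background cells (default 10,000).
#' @param seed Seed for the random background.
#' @return A list: `values` (long tibble `group`, `variable`, `value`) and
#'   `summary` (tibble of quantiles/means per group and variable).
#' @export
env_distribution_summary <- function(presences, pseudoabsences, stack,
                                     n_random = 10000, seed = 1L) {
  cells <- as_tibble.env_stack(stack)
  set.seed(seed)
  rnd <- cells[sample.int(nrow(cells), min(n_random, nrow(cells)),
                          replace = nrow(cells) < n_random), , drop = FALSE]
  grab <- function(occ, label) {
    v <- extract_stack(stack, occ$lon, occ$lat)
    v <- v[stats::complete.cases(v), , drop = FALSE]
    dplyr::mutate(tidyr::pivot_longer(v, dplyr::everything(),
                                      names_to = "variable", values_to = "value"),
                  group = label)
  }
  vals <- dplyr::bind_rows(
    grab(presences, "presence"),
    grab(pseudoabsences, "pseudoabsence"),
    dplyr::mutate(
      tidyr::pivot_longer(rnd[, names(stack$layers), drop = FALSE],
                          dplyr::everything(),
                          names_to = "variable", values_to = "value"),
      group = "random"
    )
  )[, c("group", "variable", "value")]
  summ <- dplyr::summarise(
    dplyr::group_by(vals, .data$group, .data$variable),
    n = dplyr::n(),
    mean = mean(.data$value),
    q05 = stats::quantile(.data$value, 0.05),
    q25 = stats::quantile(.data$value, 0.25),
    median = stats::median(.data$value),
    q75 = stats::quantile(.data$value, 0.75),
    q95 = stats::quantile(.data$value, 0.95),
    .groups = "drop"
  )
  list(values = vals, summary = summ)
}
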
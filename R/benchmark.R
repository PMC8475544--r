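# The niche-recovery benchmark: the package's headline end-to-end check.
#
# A synthetic species with a single-variable Gaussian niche is simulated
# under spatially biased survey effort; the full pipeline (effort KDE,
# bias-matched pseudoabsences, four learners, AUC-weighted ensemble,
# Monte-Carlo CV, response curves, permutation contributions, geomorphology
# summary) is run against it and scored against the known truth.

#' Run the synthetic niche-recovery benchmark
#'
#' Builds a seamount seascape, plants a species with a Gaussian niche in one
#' environmental variable (default: silicate, optimum 60 with sd 12) sampled
#' under hotspot-biased effort, and runs the full modeling pipeline at the
#' study configuration (10,000 pseudoabsences; BRT/GAM/Maxent/RF study
#' hyperparameters; k x 80/20 Monte-Carlo CV).
#'
#' @param seed Integer seed driving every random stage.
#' @param n_presence Presence records (default 200).
#' @param n_pseudo Pseudoabsence records (default 10,000).
#' @param k Monte-Carlo CV runs (default 10).
#' @param n_rows,n_cols Seascape grid shape (default 110 x 110).
#' @param niche_var Name of the niche variable (default "silicate").
#' @param niche_mu,niche_sd True Gaussian niche optimum and width.
#' @return A list: `evaluation` (`sdm_ensemble_evaluation`), `summary`
#'   (glance tibble), `contributions`, `curve` (ensemble response curve for
#'   the niche variable), `optimum_error_frac` (|fitted - true optimum| as a
#'   fraction of the variable's range), `top_variable`, `niche_var`,
#'   `geomorph`, `dm`, `stack`, `truth`.
#' @export
niche_recovery_benchmark <- function(seed = 1L, n_presence = 200, n_pseudo = 10000,
                                     k = 10, n_rows = 120, n_cols = 120,
                                     niche_var = "silicate",
                                     niche_mu = 60, niche_sd = 8) {
  seed <- as.integer(seed)
  # many small seamounts in a broad abyssal domain: suitable habitat ends up
  # confined to pockets covering ~1% of the seascape, as in the study system
  bathy <- make_bathymetry(n_rows = n_rows, n_cols = n_cols, n_seamounts = 12,
                           seamount_radius_km = c(2, 6), seed = seed)
  env <- make_env_fields(bathy, seed = seed + 1L)
  stack <- env$stack
  # variable-selection stage: drop anything correlated above the 0.7 screen
  corr <- correlation_matrix(stack, seed = seed)
  keep <- screen_variables(corr, threshold = 0.7)$kept
  stack <- env_stack(stack$layers[keep])
  resp <- stats::setNames(
    list(list(form = "gaussian", mu = niche_mu, sd = niche_sd)), niche_var
  )
  ref <- stack$layers[[1]]
  ext_lon <- range(grid_lons(ref)); ext_lat <- range(grid_lats(ref))
  # broad survey-effort fields spanning much more seafloor than the suitable
  # patches, as when expedition coverage follows whole ridge systems
  bias <- list(
    type = "hotspots",
    centers = rbind(
      c(ext_lon[1] + 0.3 * diff(ext_lon), ext_lat[1] + 0.35 * diff(ext_lat)),
      c(ext_lon[1] + 0.7 * diff(ext_lon), ext_lat[1] + 0.7 * diff(ext_lat))
    ),
    sd_deg = 0.3 * diff(ext_lon)
  )
  sim <- simulate_species(stack, resp, n_presence = n_presence,
                          bias_spec = bias, seed = seed + 2L)
  effort <- kde_effort_surface(sim$occurrences, ref)
  pseudo <- sample_pseudoabsences(effort, n = n_pseudo, seed = seed + 3L,
                                  exclude = sim$occurrences)
  dm <- build_design_matrix(sim$occurrences, pseudo, stack)
  ev <- cross_validate_ensemble(dm, k = k, seed = seed + 4L)
  contrib <- variable_contribution(ev$ensemble, dm, seed = seed + 5L)
  curve <- response_curve(ev$ensemble, stack, niche_var)
  rng <- range(stack$layers[[niche_var]]$values, na.rm = TRUE)
  opt_err <- abs(curve$x[which.max(curve$suitability)] - niche_mu) / diff(rng)
  suit <- predict_suitability(ev$ensemble, stack)
  masks <- make_geomorph_masks(bathy)
  geo <- threshold_and_summarize(suit, threshold = 0.7, class_masks = masks)
  list(
    evaluation = ev,
    summary = glance.sdm_ensemble_evaluation(ev),
    contributions = contrib,
    curve = curve,
    optimum_error_frac = opt_err,
    top_variable = contrib$variable[which.max(contrib$contribution)],
    niche_var = niche_var,
    geomorph = geo,
    suitability = suit,
    dm = dm,
    stack = stack,
    truth = sim$truth
  )
}
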
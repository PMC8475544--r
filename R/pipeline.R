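# Config-driven orchestration: synthetic (or file) inputs -> terrain ->
# stack -> screening -> effort KDE -> pseudoabsences -> four learners + CV ->
# AUC-weighted ensemble -> suitability, uncertainty, response curves,
# contributions, geomorphology summary. All artifacts are plain text.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    taxon = "synthetic_taxon",
    synthetic = list(
      bathymetry = list(n_rows = 90, n_cols = 90, cell_size = 0.0083,
                        n_seamounts = 5, depth_range = c(-4500, -1200)),
      species = list(
        n_presence = 150,
        response = list(
          silicate = list(form = "gaussian", mu = 60, sd = 12)
        ),
        bias = list(type = "uniform")
      )
    ),
    terrain = list(tpi_radii_m = 10000, vrm_neighborhoods = 5),
    screen = list(threshold = 0.7),
    pseudoabsence = list(n = 10000),
    cv = list(k = 10, test_fraction = 0.2),
    models = list(
      brt = list(n_trees = 1000, tree_complexity = 3, learning_rate = 0.01),
      gam = list(k = 12),
      maxent = list(beta_multiplier = 5, max_iterations = 500),
      rf = list(n_trees = 501, max_depth = 10)
    ),
    summary = list(threshold = 0.7),
    uncertainty = list(learner = "rf")
  )
}

validate_pipeline_config <- function(config) {
  required <- c("seed", "taxon", "pseudoabsence", "cv", "models", "summary")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("pipeline config lacks field(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(config$synthetic) && is.null(config$inputs)) {
    stop("pipeline config needs either a 'synthetic' block or an 'inputs' block")
  }
  if (config$cv$k < 2) stop("cv.k must be >= 2")
  if (config$pseudoabsence$n < 1) stop("pseudoabsence.n must be >= 1")
  invisible(config)
}

#' Run the full ensemble habitat-suitability pipeline
#'
#' Orchestrates every stage for one taxon and writes all artifacts (ASCII
#' grids, CSV tables, JSON manifest) to `out_dir`. The configuration is a
#' nested list or a YAML file; omitted fields fall back to study defaults
#' (10,000 pseudoabsences; BRT 1,000 trees/complexity 3; GAM thin-plate
#' k = 12; Maxent beta = 5; RF 501 trees/depth 10; 10 x 80/20 Monte-Carlo
#' CV; suitability threshold 0.7).
#'
#' @param config List or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory results (`stack`, `dm`,
#'   `evaluation`, `ensemble`, `suitability`, `uncertainty`,
#'   `contributions`, `curves`, `geomorph`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("sdm_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  # --- inputs -----------------------------------------------------------
  if (!is.null(config$synthetic)) {
    bcfg <- config$synthetic$bathymetry
    bathy <- do.call(make_bathymetry, c(bcfg, list(seed = seed)))
    env <- make_env_fields(bathy, seed = seed + 1L)
    scfg <- config$synthetic$species
    resp <- lapply(scfg$response, function(r) r)
    sim <- simulate_species(env$stack, resp, n_presence = scfg$n_presence,
                            bias_spec = scfg$bias, seed = seed + 2L,
                            taxon = config$taxon)
    presences <- sim$occurrences
    truth <- sim$truth
  } else {
    bathy <- read_grid(config$inputs$bathymetry)
    env <- list(stack = NULL)
    presences <- load_and_dedup(config$inputs$occurrences, bathy)
    truth <- NULL
  }

  # --- terrain + stack --------------------------------------------------
  terr <- terrain_suite(
    bathy,
    tpi_radii_m = config$terrain$tpi_radii_m,
    vrm_neighborhoods = config$terrain$vrm_neighborhoods
  )
  keep_terr <- c(sprintf("tpi_%g", config$terrain$tpi_radii_m),
                 sprintf("vrm_%d", config$terrain$vrm_neighborhoods), "slope")
  layers <- terr$layers[intersect(keep_terr, names(terr$layers))]
  if (!is.null(env$stack)) layers <- c(layers, env$stack$layers)
  stack <- env_stack(layers)

  # --- correlation screen ----------------------------------------------
  corr <- correlation_matrix(stack, n_sample = 20000, seed = seed)
  priority <- config$screen$priority %||% rownames(corr)
  screen <- screen_variables(corr, threshold = config$screen$threshold,
                             keep_priority = priority)
  stack <- env_stack(stack$layers[screen$kept])

  # --- effort KDE + pseudoabsences -------------------------------------
  effort <- kde_effort_surface(presences, stack$layers[[1]])
  pseudo <- sample_pseudoabsences(effort, n = config$pseudoabsence$n,
                                  seed = seed + 3L, exclude = presences,
                                  taxon = config$taxon)
  dm <- build_design_matrix(presences, pseudo, stack)

  # --- learners, CV, ensemble ------------------------------------------
  learners <- list(
    BRT = list(learner = "brt", params = config$models$brt),
    GAM = list(learner = "gam", params = config$models$gam),
    MAXENT = list(learner = "maxent", params = config$models$maxent),
    RF = list(learner = "rf", params = config$models$rf)
  )
  ev <- cross_validate_ensemble(dm, k = config$cv$k,
                                test_fraction = config$cv$test_fraction,
                                seed = seed + 4L, learners = learners)

  # --- maps, curves, contributions, summaries --------------------------
  suit <- predict_suitability(ev$ensemble, stack)
  unc <- uncertainty_map(
    list(learner = config$uncertainty$learner,
         params = config$models[[config$uncertainty$learner]]),
    dm, stack, k = config$cv$k, test_fraction = config$cv$test_fraction,
    seed = seed + 5L
  )
  curves <- response_curves(ev$ensemble, stack)
  contrib <- variable_contribution(ev$ensemble, dm, seed = seed + 6L)
  masks <- make_geomorph_masks(bathy)
  geo <- threshold_and_summarize(suit, threshold = config$summary$threshold,
                                 class_masks = masks)

  # --- artifacts --------------------------------------------------------
  write_grid(bathy, file.path(out_dir, "bathymetry.asc"))
  write_grid(effort, file.path(out_dir, "effort_kde.asc"))
  write_grid(suit, file.path(out_dir, "suitability_ensemble.asc"))
  write_grid(unc, file.path(out_dir, "uncertainty.asc"))
  utils::write.csv(presences, file.path(out_dir, "presences.csv"), row.names = FALSE)
  utils::write.csv(pseudo, file.path(out_dir, "pseudoabsences.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(corr), file.path(out_dir, "correlation_matrix.csv"))
  utils::write.csv(ev$runs, file.path(out_dir, "evaluation_runs.csv"), row.names = FALSE)
  utils::write.csv(glance.sdm_ensemble_evaluation(ev),
                   file.path(out_dir, "evaluation_summary.csv"), row.names = FALSE)
  utils::write.csv(curves, file.path(out_dir, "response_curves.csv"), row.names = FALSE)
  utils::write.csv(contrib, file.path(out_dir, "contributions.csv"), row.names = FALSE)
  utils::write.csv(geo, file.path(out_dir, "geomorph_summary.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("benthosdm")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = rlang::hash(config),
    config = config,
    n_presence = nrow(presences),
    n_pseudoabsence = nrow(pseudo),
    variables = names(stack$layers),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    out_dir = out_dir, config = config, bathy = bathy, stack = stack,
    presences = presences, pseudoabsences = pseudo, effort = effort,
    dm = dm, evaluation = ev, ensemble = ev$ensemble, suitability = suit,
    uncertainty = unc, curves = curves, contributions = contrib,
    screen = screen, geomorph = geo, truth = truth, manifest = manifest
  ))
}
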
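# Performance metrics (AUC, TSS), the Monte-Carlo cross-validation harness,
# per-cell uncertainty maps, and thresholded geomorphology summaries.

#' Area under the ROC curve for presence vs background scores
#'
#' The rank-sum (Mann-Whitney) probability that a random presence outscores a
#' random background point, with ties counted one half.
#'
#' @param presence_scores,background_scores Numeric score vectors (non-empty).
#' @return AUC in [0, 1].
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0 || n0 == 0) stop("both score groups must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' TSS(t) = sensitivity(t) + specificity(t) - 1, classifying scores >= t as
#' presence. `"maximize"` scans the midpoints between consecutive distinct
#' scores (plus the all-presence endpoint) and returns the maximum; a fixed
#' threshold evaluates TSS at `t`.
#'
#' @param presence_scores,background_scores Numeric score vectors (non-empty).
#' @param threshold_policy `"maximize"` or `"fixed"`.
#' @param t Threshold when `threshold_policy = "fixed"`.
#' @return A list: `tss` in [-1, 1] and `threshold`.
#' @export
tss <- function(presence_scores, background_scores,
                threshold_policy = c("maximize", "fixed"), t = NULL) {
  threshold_policy <- match.arg(threshold_policy)
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0 || n0 == 0) stop("both score groups must be non-empty")
  tss_at <- function(th) {
    mean(presence_scores >= th) + mean(background_scores < th) - 1
  }
  if (threshold_policy == "fixed") {
    if (is.null(t)) stop("fixed threshold policy needs t")
    return(list(tss = tss_at(t), threshold = t))
  }
  s <- sort(unique(c(presence_scores, background_scores)))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s)
  vals <- vapply(cand, tss_at, numeric(1))
  best <- which.max(vals)
  list(tss = vals[best], threshold = cand[best])
}

# resolve a learner spec ("brt" | "gam" | "maxent" | "rf" | list(learner=,
# params=)) to a fitting closure f(dm, seed)
resolve_learner <- function(spec) {
  if (is.character(spec)) spec <- list(learner = spec, params = list())
  learner <- tolower(spec$learner)
  params <- if (is.null(spec$params)) list() else spec$params
  fitter <- switch(
    learner,
    brt = function(dm, seed) fit_brt(dm, params, seed),
    gam = function(dm, seed) fit_gam(dm, params),
    maxent = function(dm, seed) fit_maxent(dm, params),
    rf = function(dm, seed) fit_rf(dm, params, seed),
    stop("unknown learner: ", spec$learner)
  )
  list(name = toupper(learner), fit = fitter)
}

# recompute prevalence weights after subsetting rows
reweight_design <- function(dm) {
  n <- nrow(dm); n1 <- sum(dm$y == 1); n0 <- n - n1
  dm$weight <- ifelse(dm$y == 1, n / (2 * n1), n / (2 * n0))
  dm
}

# one stratified Monte-Carlo 80/20 split; returns train/test row indices
mc_split <- function(y, test_fraction) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  t1 <- sample(idx1, max(1, round(test_fraction * length(idx1))))
  t0 <- sample(idx0, max(1, round(test_fraction * length(idx0))))
  test <- c(t1, t0)
  list(train = setdiff(seq_along(y), test), test = test)
}

score_split <- function(model, dm, rows) {
  scores <- predict(model, dm[rows, , drop = FALSE])
  y <- dm$y[rows]
  ts <- tss(scores[y == 1], scores[y == 0])
  list(auc = auc(scores[y == 1], scores[y == 0]), tss = ts$tss, threshold = ts$threshold)
}

#' Monte-Carlo cross-validation of one learner
#'
#' `k` independent random splits withhold `test_fraction` of the presences
#' and of the pseudoabsences (resampled with replacement between runs, not
#' disjoint folds); the learner is refit on each training portion, scored on
#' the held-out portion (AUC and maximized TSS), and finally refit on the
#' full data, whose training-data AUC/TSS are also reported.
#'
#' @param learner `"brt"`, `"gam"`, `"maxent"`, `"rf"`, or a list
#'   `list(learner =, params =)`.
#' @param dm An `sdm_design` tibble.
#' @param k Number of runs (study default 10).
#' @param test_fraction Held-out fraction per run (default 0.2).
#' @param seed Integer seed; fully determines the splits and fits.
#' @return An `sdm_evaluation`: per-run metrics, training metrics, and the
#'   final full-data model.
#' @export
cross_validate <- function(learner, dm, k = 10, test_fraction = 0.2, seed = 1L) {
  stopifnot(k >= 2, test_fraction > 0, test_fraction < 1)
  check_two_classes(dm)
  lr <- resolve_learner(learner)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max / 2, k)
  runs <- purrr::map_dfr(seq_len(k), function(i) {
    set.seed(run_seeds[i])
    sp <- mc_split(dm$y, test_fraction)
    model <- lr$fit(reweight_design(dm[sp$train, , drop = FALSE]), run_seeds[i])
    sc <- score_split(model, dm, sp$test)
    tibble::tibble(run = i, auc = sc$auc, tss = sc$tss, threshold = sc$threshold)
  })
  final <- lr$fit(dm, seed)
  tr <- score_split(final, dm, seq_len(nrow(dm)))
  structure(
    list(
      learner = lr$name, k = k, test_fraction = test_fraction, seed = seed,
      runs = runs,
      training = tibble::tibble(auc = tr$auc, tss = tr$tss, threshold = tr$threshold),
      model = final
    ),
    class = "sdm_evaluation"
  )
}

#' @export
print.sdm_evaluation <- function(x, ...) {
  cat(sprintf(
    "<sdm_evaluation %s> %d runs: test AUC %.3f +/- %.3f, TSS %.3f +/- %.3f; training AUC %.3f, TSS %.3f\n",
    x$learner, x$k, mean(x$runs$auc), stats::sd(x$runs$auc),
    mean(x$runs$tss), stats::sd(x$runs$tss), x$training$auc, x$training$tss
  ))
  invisible(x)
}

#' Per-run and summary views of an evaluation
#'
#' `tidy()` returns the per-run test metrics; `glance()` a one-row summary
#' with means, standard deviations and the full-data training metrics.
#'
#' @param x An `sdm_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdm_evaluation <- function(x, ...) {
  dplyr::mutate(x$runs, learner = x$learner, .before = 1)
}

#' @rdname tidy.sdm_evaluation
#' @export
glance.sdm_evaluation <- function(x, ...) {
  tibble::tibble(
    learner = x$learner,
    k = x$k,
    test_auc_mean = mean(x$runs$auc),
    test_auc_sd = stats::sd(x$runs$auc),
    test_tss_mean = mean(x$runs$tss),
    test_tss_sd = stats::sd(x$runs$tss),
    training_auc = x$training$auc,
    training_tss = x$training$tss
  )
}

#' Cross-validate all four learners and the AUC-weighted ensemble together
#'
#' Shares one set of Monte-Carlo splits across learners: in each run all
#' members are fit on the same training portion, scored on the same held-out
#' portion, and combined (weights from the members' training-portion AUCs)
#' into an ensemble that is scored on the held-out portion too. The final
#' full-data members and ensemble are also fit and scored on training data.
#'
#' @param dm An `sdm_design` tibble.
#' @param k Number of Monte-Carlo runs (default 10).
#' @param test_fraction Held-out fraction per run (default 0.2).
#' @param seed Integer seed.
#' @param learners Named list of learner specs (default the study's four).
#' @return An `sdm_ensemble_evaluation`: `runs` (long tibble of per-run,
#'   per-model test metrics), `training` (full-data metrics per model),
#'   `ensemble` (final `sdm_ensemble`), `members` (final fits).
#' @export
cross_validate_ensemble <- function(dm, k = 10, test_fraction = 0.2, seed = 1L,
                                    learners = list(BRT = "brt", GAM = "gam",
                                                    MAXENT = "maxent", RF = "rf")) {
  stopifnot(k >= 2)
  check_two_classes(dm)
  specs <- lapply(learners, resolve_learner)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max / 2, k)
  runs <- purrr::map_dfr(seq_len(k), function(i) {
    set.seed(run_seeds[i])
    sp <- mc_split(dm$y, test_fraction)
    train <- reweight_design(dm[sp$train, , drop = FALSE])
    fits <- lapply(specs, function(s) s$fit(train, run_seeds[i]))
    member_rows <- purrr::map_dfr(names(fits), function(nm) {
      sc <- score_split(fits[[nm]], dm, sp$test)
      tibble::tibble(run = i, model = nm, auc = sc$auc, tss = sc$tss)
    })
    train_aucs <- vapply(fits, function(f) {
      score_split(f, dm, sp$train)$auc
    }, numeric(1))
    ens <- build_ensemble(fits, train_aucs)
    sc <- score_split(ens, dm, sp$test)
    dplyr::bind_rows(
      member_rows,
      tibble::tibble(run = i, model = "Ensemble", auc = sc$auc, tss = sc$tss)
    )
  })
  final_fits <- lapply(specs, function(s) s$fit(dm, seed))
  final_train <- purrr::map_dfr(names(final_fits), function(nm) {
    sc <- score_split(final_fits[[nm]], dm, seq_len(nrow(dm)))
    tibble::tibble(model = nm, auc = sc$auc, tss = sc$tss)
  })
  ens <- build_ensemble(final_fits, final_train$auc)
  sc <- score_split(ens, dm, seq_len(nrow(dm)))
  training <- dplyr::bind_rows(
    final_train, tibble::tibble(model = "Ensemble", auc = sc$auc, tss = sc$tss)
  )
  structure(
    list(runs = runs, training = training, ensemble = ens,
         members = final_fits, k = k, seed = seed),
    class = "sdm_ensemble_evaluation"
  )
}

#' @export
print.sdm_ensemble_evaluation <- function(x, ...) {
  cat("<sdm_ensemble_evaluation>", x$k, "runs\n")
  print(glance.sdm_ensemble_evaluation(x))
  invisible(x)
}

#' @rdname tidy.sdm_evaluation
#' @export
tidy.sdm_ensemble_evaluation <- function(x, ...) x$runs

#' @rdname tidy.sdm_evaluation
#' @export
glance.sdm_ensemble_evaluation <- function(x, ...) {
  test <- dplyr::summarise(
    dplyr::group_by(x$runs, .data$model),
    test_auc_mean = mean(.data$auc), test_auc_sd = stats::sd(.data$auc),
    test_tss_mean = mean(.data$tss), test_tss_sd = stats::sd(.data$tss),
    .groups = "drop"
  )
  dplyr::left_join(
    test,
    dplyr::rename(x$training, training_auc = "auc", training_tss = "tss"),
    by = "model"
  )
}

#' Spatial uncertainty map from resampled model runs
#'
#' Refits the learner on `k` random subsets each withholding `test_fraction`
#' of the presence and pseudoabsence rows, predicts each refit over the
#' stack, and returns the per-cell standard deviation of the `k` suitability
#' maps: where the prediction is sensitive to the sampling of occurrences
#' and pseudoabsences, the SD is high.
#'
#' @param learner Learner spec as in [cross_validate()].
#' @param dm An `sdm_design` tibble.
#' @param stack An `env_stack` to predict over.
#' @param k Number of resampled runs (default 10).
#' @param test_fraction Withheld fraction per run (default 0.2).
#' @param seed Integer seed.
#' @return A `bgrid` of per-cell SDs (nodata where any predictor is masked).
#' @export
uncertainty_map <- function(learner, dm, stack, k = 10, test_fraction = 0.2, seed = 1L) {
  lr <- resolve_learner(learner)
  cells <- as_tibble.env_stack(stack)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max / 2, k)
  preds <- vapply(seq_len(k), function(i) {
    set.seed(run_seeds[i])
    sp <- mc_split(dm$y, test_fraction)
    model <- lr$fit(reweight_design(dm[sp$train, , drop = FALSE]), run_seeds[i])
    predict(model, cells)
  }, numeric(nrow(cells)))
  sds <- apply(preds, 1, stats::sd)
  ref <- stack$layers[[1]]
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  out[cbind(cells$row, cells$col)] <- sds
  grid_like(ref, out, name = sprintf("uncertainty_%s", lr$name))
}

#' Per-cell SD across prediction maps
#'
#' Building block for uncertainty maps when run-specific suitability grids
#' already exist.
#'
#' @param grids List of aligned `bgrid`s (>= 2).
#' @return A `bgrid` of per-cell standard deviations.
#' @export
grid_sd <- function(grids) {
  stopifnot(length(grids) >= 2)
  ref <- grids[[1]]
  arr <- vapply(grids, function(g) {
    stopifnot(same_geometry(g, ref))
    as.vector(g$values)
  }, numeric(length(ref$values)))
  sds <- apply(arr, 1, stats::sd)
  grid_like(ref, matrix(sds, nrow(ref$values), ncol(ref$values)), name = "sd")
}

#' Share of highly suitable habitat per geomorphic class
#'
#' Thresholds the suitability map (suitability > `threshold` = "highly
#' suitable") and reports, per class mask, the class's area of highly
#' suitable cells as a percentage of all highly suitable area. Classes may
#' overlap spatially, so percentages can sum to more than 100.
#'
#' @param suitability A suitability `bgrid`.
#' @param threshold Suitability cutoff in (0, 1); study default 0.7.
#' @param class_masks Named list of aligned `bgrid`s, nonzero/TRUE inside the
#'   class.
#' @param areas Optional per-cell area `bgrid`; defaults to
#'   [cell_area_km2()].
#' @return A tibble `class`, `area_km2`, `percent_of_suitable`, with
#'   attribute `total_suitable_km2`. Zero rows of percent when nothing
#'   exceeds the threshold.
#' @export
threshold_and_summarize <- function(suitability, threshold = 0.7, class_masks,
                                    areas = NULL) {
  stopifnot(threshold > 0, threshold < 1, length(class_masks) >= 1)
  if (is.null(areas)) areas <- cell_area_km2(suitability)
  high <- !is.na(suitability$values) & suitability$values > threshold
  total <- sum(areas$values[high])
  rows <- purrr::map_dfr(names(class_masks), function(nm) {
    mask <- class_masks[[nm]]
    stopifnot(same_geometry(mask, suitability))
    inside <- high & !is.na(mask$values) & mask$values != 0
    a <- sum(areas$values[inside])
    tibble::tibble(
      class = nm,
      area_km2 = a,
      percent_of_suitable = if (total > 0) 100 * a / total else 0
    )
  })
  attr(rows, "total_suitable_km2") <- total
  attr(rows, "any_suitable") <- total > 0
  rows
}
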
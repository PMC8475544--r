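# AUC-weighted ensembles, suitability maps, response curves, and permutation
# variable contributions.

#' Combine fitted models into an AUC-weighted ensemble
#'
#' Member weights are w_i = AUC_i / sum(AUC), so the ensemble prediction is a
#' convex combination of member suitability scores.
#'
#' @param members List of `sdm_fit` objects (>= 2).
#' @param aucs One AUC per member, each in (0, 1].
#' @return An `sdm_ensemble` with `members`, `weights`, `weight_basis`.
#' @export
build_ensemble <- function(members, aucs) {
  if (length(members) < 2) stop("an ensemble needs at least 2 members")
  if (length(aucs) != length(members)) {
    stop("need exactly one AUC per member (", length(members), " members, ",
         length(aucs), " AUCs)")
  }
  if (any(aucs <= 0 | aucs > 1)) stop("AUC weights must lie in (0, 1]")
  vars <- unique(unlist(lapply(members, `[[`, "vars")))
  nm <- names(members)
  if (is.null(nm)) nm <- vapply(members, `[[`, character(1), "learner")
  names(members) <- nm
  structure(
    list(
      members = members,
      weights = stats::setNames(aucs / sum(aucs), nm),
      weight_basis = stats::setNames(aucs, nm),
      vars = vars,
      medians = members[[1]]$medians
    ),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("<sdm_ensemble>", length(x$members), "members\n")
  for (nm in names(x$members)) {
    cat(sprintf("  %-8s weight %.3f (AUC %.3f)\n", nm, x$weights[nm], x$weight_basis[nm]))
  }
  invisible(x)
}

#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, function(m) predict(m, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1) preds <- matrix(preds, nrow = 1)
  as.numeric(preds %*% object$weights)
}

#' @rdname tidy.sdm_fit
#' @export
tidy.sdm_ensemble <- function(x, ...) {
  tibble::tibble(
    member = names(x$members),
    weight = as.numeric(x$weights),
    auc = as.numeric(x$weight_basis)
  )
}

#' @rdname tidy.sdm_fit
#' @export
glance.sdm_ensemble <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members),
    members = paste(names(x$members), collapse = "+"),
    n_predictors = length(x$vars)
  )
}

#' Map habitat suitability over a predictor stack
#'
#' Predicts the model at every jointly unmasked cell of the stack; cells with
#' any masked predictor stay nodata.
#'
#' @param model An `sdm_fit` or `sdm_ensemble`.
#' @param stack An `env_stack` containing all training predictors.
#' @return A `bgrid` of suitability in [0, 1].
#' @export
predict_suitability <- function(model, stack) {
  missing <- setdiff(model$vars, names(stack$layers))
  if (length(missing) > 0) {
    stop("stack lacks predictor(s): ", paste(missing, collapse = ", "))
  }
  cells <- as_tibble.env_stack(stack)
  ref <- stack$layers[[1]]
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  if (nrow(cells) > 0) {
    out[cbind(cells$row, cells$col)] <- predict(model, cells)
  }
  grid_like(ref, out, name = "suitability")
}

#' Evaluation-strip response curve
#'
#' Varies one predictor across its observed range in the stack while holding
#' all others at their training medians, tracing how predicted suitability
#' responds to that variable alone.
#'
#' @param model An `sdm_fit` or `sdm_ensemble` (training medians are stored at
#'   fit time).
#' @param stack An `env_stack` supplying the observed variable range.
#' @param variable Predictor name.
#' @param n_points Curve resolution (default 100).
#' @return A tibble `variable`, `x`, `suitability`.
#' @export
response_curve <- function(model, stack, variable, n_points = 100) {
  if (!variable %in% model$vars) {
    stop("'", variable, "' was not a training variable of this model")
  }
  if (!variable %in% names(stack$layers)) {
    stop("stack lacks layer '", variable, "'")
  }
  rng <- range(stack$layers[[variable]]$values, na.rm = TRUE)
  xs <- seq(rng[1], rng[2], length.out = n_points)
  nd <- tibble::as_tibble(as.list(model$medians))[rep(1, n_points), , drop = FALSE]
  nd[[variable]] <- xs
  tibble::tibble(variable = variable, x = xs, suitability = predict(model, nd))
}

#' Response curves for every training variable
#'
#' @inheritParams response_curve
#' @return A long tibble of curves for all training variables.
#' @export
response_curves <- function(model, stack, n_points = 100) {
  dplyr::bind_rows(lapply(model$vars, function(v) {
    response_curve(model, stack, v, n_points)
  }))
}

#' Permutation variable contributions
#'
#' For each variable, its values are permuted and the drop in fit,
#' 1 - cor(original predictions, permuted predictions), is averaged over
#' `n_permutations` shuffles; drops are rescaled to percentages summing
#' to 100. Variables the model ignores score ~0%.
#'
#' @param model An `sdm_fit` or `sdm_ensemble`.
#' @param dm The `sdm_design` tibble to permute over.
#' @param n_permutations Shuffles per variable (default 5).
#' @param seed Integer seed.
#' @return A tibble `variable`, `importance` (raw mean drop), `contribution`
#'   (percent).
#' @export
variable_contribution <- function(model, dm, n_permutations = 5, seed = 1L) {
  if (nrow(dm) == 0) stop("design matrix is empty")
  vars <- model$vars
  base_pred <- predict(model, dm)
  set.seed(seed)
  imp <- vapply(vars, function(v) {
    drops <- vapply(seq_len(n_permutations), function(i) {
      shuffled <- dm
      shuffled[[v]] <- sample(shuffled[[v]])
      perm_pred <- predict(model, shuffled)
      if (stats::sd(perm_pred) == 0 || stats::sd(base_pred) == 0) {
        return(if (all(perm_pred == base_pred)) 0 else 1)
      }
      1 - stats::cor(base_pred, perm_pred)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) {
    warning("no variable had measurable importance; returning uniform percentages")
    pct <- rep(100 / length(vars), length(vars))
  } else {
    pct <- 100 * imp / sum(imp)
  }
  tibble::tibble(variable = vars, importance = unname(imp), contribution = unname(pct))
}
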
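# The four presence-background learners and the shared fitted-model surface.
#
# Every learner returns an `sdm_fit` whose predict() maps a tibble of
# predictor columns to a habitat suitability score in [0, 1]. Hyperparameter
# defaults are the study configuration: BRT >= 1,000 trees, Bernoulli loss,
# tree complexity 3; GAM thin-plate smooths with basis dimension 12,
# binomial; Maxent regularization multiplier beta = 5, iteration cap 500;
# RF 501 trees, depth cap 10, mtry = floor(sqrt(p)).

new_sdm_fit <- function(learner, fit, vars, params, seed = NA_integer_,
                        medians = NULL, extra = list()) {
  structure(
    c(list(learner = learner, fit = fit, vars = vars, params = params,
           seed = seed, medians = medians), extra),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit %s> %d predictors: %s\n",
              x$learner, length(x$vars), paste(x$vars, collapse = ", ")))
  invisible(x)
}

check_two_classes <- function(dm) {
  if (!any(dm$y == 1) || !any(dm$y == 0)) {
    stop("design matrix must contain both presences and pseudoabsences")
  }
}

design_medians <- function(dm, vars) {
  vapply(vars, function(v) stats::median(dm[[v]]), numeric(1))
}

#' Fit a boosted regression tree model
#'
#' Gradient boosting with Bernoulli (logistic) loss and tree complexity 3
#' (interaction depth of the member trees). The tree count has a floor of
#' 1,000; a deliberately small learning rate keeps each tree's contribution
#' modest.
#'
#' @param dm An `sdm_design` tibble.
#' @param params List overriding `n_trees` (>= 1000), `tree_complexity` (3),
#'   `learning_rate` (0.01).
#' @param seed Integer seed.
#' @return An `sdm_fit`.
#' @export
fit_brt <- function(dm, params = list(), seed = 1L) {
  check_two_classes(dm)
  p <- utils::modifyList(
    list(n_trees = 1000, tree_complexity = 3, learning_rate = 0.01), params
  )
  p$n_trees <- max(p$n_trees, 1000)
  vars <- design_predictors(dm)
  X <- as.matrix(dm[, vars, drop = FALSE])
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = dm$y, weight = dm$weight)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      max_depth = p$tree_complexity,
      eta = p$learning_rate,
      nthread = 1,
      seed = seed
    ),
    data = dtrain,
    nrounds = p$n_trees,
    verbose = 0
  )
  new_sdm_fit("BRT", booster, vars, p, seed, design_medians(dm, vars))
}

#' Fit a binomial additive model
#'
#' One thin-plate regression spline per predictor with basis dimension 12
#' (penalized, so effective degrees of freedom are at most 12), logit link.
#' The basis is shrunk automatically for predictors with too few distinct
#' values.
#'
#' @param dm An `sdm_design` tibble.
#' @param params List overriding `k` (spline basis dimension, 12).
#' @return An `sdm_fit`.
#' @export
fit_gam <- function(dm, params = list()) {
  check_two_classes(dm)
  p <- utils::modifyList(list(k = 12), params)
  vars <- design_predictors(dm)
  terms <- vapply(vars, function(v) {
    nu <- length(unique(dm[[v]]))
    if (nu > 3) {
      sprintf("s(%s, bs = 'tp', k = %d)", v, min(p$k, nu - 1))
    } else {
      v  # too few distinct values to smooth: enter linearly
    }
  }, character(1))
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  dat <- as.data.frame(dm[, c("y", vars)])
  w <- dm$weight
  fit <- tryCatch(
    suppressWarnings(  # non-integer binomial weights are intentional
      mgcv::gam(form, family = stats::binomial(), data = dat, weights = w,
                method = "REML")
    ),
    error = function(e) stop("GAM fit failed (rank deficiency?): ", conditionMessage(e))
  )
  new_sdm_fit("GAM", fit, vars, p, medians = design_medians(dm, vars))
}

#' Fit a random forest model
#'
#' 501 probability trees with depth capped at 10 and mtry = floor(sqrt(p));
#' class imbalance is countered with the design matrix's prevalence weights.
#' Suitability is the fraction of trees voting presence.
#'
#' @param dm An `sdm_design` tibble.
#' @param params List overriding `n_trees` (501), `max_depth` (10), `mtry`.
#' @param seed Integer seed.
#' @return An `sdm_fit`.
#' @export
fit_rf <- function(dm, params = list(), seed = 1L) {
  check_two_classes(dm)
  vars <- design_predictors(dm)
  p <- utils::modifyList(
    list(n_trees = 501, max_depth = 10, mtry = floor(sqrt(length(vars)))), params
  )
  dat <- as.data.frame(dm[, c("y", vars)])
  dat$y <- factor(dat$y, levels = c(0, 1))
  fit <- ranger::ranger(
    y ~ ., data = dat,
    num.trees = p$n_trees,
    max.depth = p$max_depth,
    mtry = p$mtry,
    probability = TRUE,
    case.weights = dm$weight,
    seed = seed,
    num.threads = 1
  )
  new_sdm_fit("RF", fit, vars, p, seed, design_medians(dm, vars))
}

# maximum depth actually reached by any tree of a ranger forest
rf_max_depth <- function(model) {
  stopifnot(inherits(model, "sdm_fit"), model$learner == "RF")
  max(vapply(seq_len(model$fit$num.trees), function(t) {
    info <- ranger::treeInfo(model$fit, t)
    depth <- rep(0L, nrow(info))
    for (i in seq_len(nrow(info))) {
      kids <- c(info$leftChild[i], info$rightChild[i])
      kids <- kids[!is.na(kids)] + 1L  # treeInfo children are 0-based
      depth[kids] <- depth[i] + 1L
    }
    max(depth)
  }, integer(1)))
}

#' Predict habitat suitability for new records
#'
#' @param object An `sdm_fit`.
#' @param newdata Tibble/data frame containing the training predictors.
#' @param ... Unused.
#' @return Numeric vector of suitability scores in [0, 1].
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  missing <- setdiff(object$vars, names(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "))
  }
  nd <- newdata[, object$vars, drop = FALSE]
  p <- switch(
    object$learner,
    BRT = predict(object$fit, xgboost::xgb.DMatrix(as.matrix(nd))),
    GAM = as.numeric(mgcv::predict.gam(object$fit, newdata = as.data.frame(nd),
                                       type = "response")),
    RF = predict(object$fit, data = as.data.frame(nd),
                 num.threads = 1)$predictions[, "1"],
    MAXENT = predict_maxent(object, nd),
    stop("unknown learner: ", object$learner)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Summaries of a fitted suitability model
#'
#' `tidy()` lists per-term information where the learner exposes it (GAM
#' smooth EDFs, Maxent nonzero features, tree-model variable usage);
#' `glance()` gives a one-row model description.
#'
#' @param x An `sdm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdm_fit <- function(x, ...) {
  switch(
    x$learner,
    GAM = {
      s <- summary(x$fit)
      tibble::tibble(
        term = rownames(s$s.table),
        edf = s$s.table[, "edf"],
        statistic = s$s.table[, "Chi.sq"],
        p.value = s$s.table[, "p-value"]
      )
    },
    MAXENT = tibble::tibble(
      term = names(x$betas), estimate = as.numeric(x$betas)
    ),
    BRT = {
      imp <- xgboost::xgb.importance(model = x$fit)
      tibble::tibble(term = imp$Feature, gain = imp$Gain)
    },
    RF = tibble::tibble(term = x$vars)
  )
}

#' @rdname tidy.sdm_fit
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble::tibble(
    learner = x$learner,
    n_predictors = length(x$vars),
    params = paste(names(x$params), unlist(x$params), sep = "=", collapse = "; "),
    seed = x$seed
  )
}
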
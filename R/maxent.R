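# Maximum-entropy suitability model via its penalized-logistic equivalence.
#
# The maximum-entropy density over background cells subject to feature
# expectation constraints is equivalent to an L1-penalized infinitely
# weighted logistic regression of presences against background. The model
# here builds linear, quadratic and hinge features from each predictor
# (scaled to the training range), applies per-feature L1 penalties scaled by
# the regularization multiplier beta, and solves the penalized problem with
# coordinate descent (glmnet). Predictions use the complementary log-log
# transform of the exponential model, giving suitability in [0, 1].

maxent_feature_names <- function(vars, n_hinge) {
  unlist(lapply(vars, function(v) {
    c(paste0(v, ":lin"), paste0(v, ":quad"),
      paste0(v, ":hingeF", seq_len(n_hinge)),
      paste0(v, ":hingeR", seq_len(n_hinge)))
  }))
}

# expand predictors into the maxent feature matrix; ranges fix the scaling
maxent_features <- function(data, vars, ranges, n_hinge) {
  knots <- seq(0, 1, length.out = n_hinge + 2)[2:(n_hinge + 1)]
  cols <- lapply(vars, function(v) {
    rg <- ranges[[v]]
    s <- (data[[v]] - rg[1]) / max(rg[2] - rg[1], .Machine$double.eps)
    s <- pmin(pmax(s, 0), 1)  # clamp outside the training range
    fwd <- vapply(knots, function(t) pmax(0, s - t) / (1 - t), numeric(length(s)))
    rev <- vapply(knots, function(t) pmax(0, t - s) / t, numeric(length(s)))
    cbind(s, s^2, fwd, rev)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- maxent_feature_names(vars, n_hinge)
  X
}

#' Fit a maximum-entropy model
#'
#' Presence rows are contrasted against the pseudoabsence rows of the design
#' matrix, which serve as the background sample. `beta_multiplier` scales the
#' per-feature L1 penalties (hinge features carry half the base penalty of
#' linear/quadratic features, following the original software's defaults);
#' larger beta gives smoother, simpler models. If the coordinate-descent
#' solver has not converged within the iteration budget the model is flagged
#' (`converged = FALSE`) but still returned.
#'
#' @param dm An `sdm_design` tibble (pseudoabsences are the background).
#' @param params List overriding `beta_multiplier` (5), `max_iterations`
#'   (500), `n_hinge` (10 hinge knots per direction and variable).
#' @return An `sdm_fit` with elements `betas`, `alpha`, `entropy`,
#'   `converged`.
#' @export
fit_maxent <- function(dm, params = list()) {
  check_two_classes(dm)
  p <- utils::modifyList(
    list(beta_multiplier = 5, max_iterations = 500, n_hinge = 10), params
  )
  vars <- design_predictors(dm)
  ranges <- lapply(stats::setNames(vars, vars), function(v) range(dm[[v]]))
  X <- maxent_features(dm, vars, ranges, p$n_hinge)
  y <- dm$y
  w <- ifelse(y == 1, 1, 100)  # approximates the infinite-weight background limit
  # default per-feature L1 penalties: a class base interpolated on the number
  # of presences, scaled by the feature's spread over presence sites (the
  # original software's regularization semantics), times the beta multiplier
  np <- sum(y == 1)
  lin_base <- stats::approx(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05), np, rule = 2)$y
  quad_base <- stats::approx(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05),
                             np, rule = 2)$y
  base <- ifelse(grepl(":hinge", colnames(X)), 0.5,
                 ifelse(grepl(":quad", colnames(X)), quad_base, lin_base))
  sd_pres <- apply(X[y == 1, , drop = FALSE], 2, stats::sd)
  reg <- pmax(base * pmax(sd_pres, 1e-4) / sqrt(np), 1e-6) * p$beta_multiplier
  lambda <- 10^seq(4, 0, length.out = 200) * mean(reg) * sum(y) / sum(w)
  old_ctl <- glmnet::glmnet.control()
  glmnet::glmnet.control(pmin = 1e-8, fdev = 0)  # keep the full lambda path
  on.exit(do.call(glmnet::glmnet.control, old_ctl[c("pmin", "fdev")]), add = TRUE)
  fit <- glmnet::glmnet(
    X, y, family = "binomial", weights = w,
    penalty.factor = reg, lambda = lambda, standardize = FALSE,
    maxit = p$max_iterations * 200
  )
  converged <- length(fit$lambda) == length(lambda)
  betas <- fit$beta[, ncol(fit$beta)]
  eta_bg <- as.numeric(X[y == 0, , drop = FALSE] %*% betas)
  alpha <- -log(sum(exp(eta_bg)))
  pr <- exp(eta_bg + alpha)
  entropy <- -sum(pr * log(pmax(pr, .Machine$double.xmin)))
  new_sdm_fit(
    "MAXENT", fit, vars, p, medians = design_medians(dm, vars),
    extra = list(
      betas = betas, alpha = alpha, entropy = entropy,
      ranges = ranges, converged = converged
    )
  )
}

# cloglog output of the exponential model, normalized over the background
predict_maxent <- function(model, newdata) {
  X <- maxent_features(newdata, model$vars, model$ranges, model$params$n_hinge)
  eta <- as.numeric(X %*% model$betas)
  1 - exp(-exp(eta + model$alpha + model$entropy))
}
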
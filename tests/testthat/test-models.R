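# The four learners, the AUC-weighted ensemble, response curves and
# permutation contributions.

# design matrix with a monotone suitability signal in x1
signal_dm <- function(n1 = 60, n0 = 240, seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  x1 <- c(rnorm(n1, 2, 0.7), rnorm(n0, 0, 1))
  x2 <- rnorm(n)
  x3 <- rnorm(n)
  dm <- tibble::tibble(
    lon = runif(n), lat = -runif(n),
    y = rep(c(1, 0), c(n1, n0)),
    weight = rep(c(n / (2 * n1), n / (2 * n0)), c(n1, n0)),
    x1 = x1, x2 = x2, x3 = x3
  )
  attr(dm, "predictors") <- c("x1", "x2", "x3")
  class(dm) <- c("sdm_design", class(dm))
  dm
}

stack_from_dm <- function(dm, nrc = 12) {
  set.seed(2)
  mk <- function(v) bgrid(matrix(sample(v, nrc^2, TRUE), nrc, nrc), 0, 0, 0.05)
  env_stack(list(x1 = mk(dm$x1), x2 = mk(dm$x2), x3 = mk(dm$x3)))
}

test_that("every learner achieves near-perfect training AUC on separable data", {
  set.seed(10)
  n1 <- 50; n0 <- 200; n <- n1 + n0
  dm <- tibble::tibble(
    lon = runif(n), lat = runif(n),
    y = rep(c(1, 0), c(n1, n0)),
    weight = rep(c(n / (2 * n1), n / (2 * n0)), c(n1, n0)),
    x1 = c(runif(n1, 2, 3), runif(n0, 0, 1)),  # disjoint supports
    x2 = rnorm(n)
  )
  attr(dm, "predictors") <- c("x1", "x2")
  class(dm) <- c("sdm_design", class(dm))
  models <- list(
    fit_brt(dm, seed = 1),
    fit_gam(dm),
    fit_maxent(dm, list(beta_multiplier = 1)),
    fit_rf(dm, seed = 1)
  )
  for (m in models) {
    p <- predict(m, dm)
    expect_true(all(p >= 0 & p <= 1), info = m$learner)
    expect_gt(auc(p[dm$y == 1], p[dm$y == 0]), 0.98)
  }
})

test_that("learners fail cleanly on single-class data and missing predictors", {
  dm <- signal_dm()
  dm1 <- dm[dm$y == 1, ]
  expect_error(fit_brt(dm1), "both")
  expect_error(fit_rf(dm1), "both")
  m <- fit_rf(dm, seed = 1)
  expect_error(predict(m, dm[, c("x1", "x2")]), "x3")
})

test_that("BRT honors the 1,000-tree floor and fixed seeds reproduce fits", {
  dm <- signal_dm()
  m <- fit_brt(dm, list(n_trees = 10), seed = 3)  # floor overrides the request
  expect_gte(m$params$n_trees, 1000)
  expect_equal(xgboost::xgb.get.num.boosted.rounds(m$fit), m$params$n_trees)
  m2 <- fit_brt(dm, seed = 5)
  m3 <- fit_brt(dm, seed = 5)
  expect_identical(predict(m2, dm), predict(m3, dm))
})

test_that("BRT recovers a monotone response over the central range", {
  dm <- signal_dm(n1 = 150, n0 = 600)
  m <- fit_brt(dm, seed = 2)
  st <- stack_from_dm(dm)
  rc <- response_curve(m, st, "x1", n_points = 50)
  central <- rc[rc$x >= stats::quantile(dm$x1, 0.1) &
                  rc$x <= stats::quantile(dm$x1, 0.9), ]
  # increasing overall trend across the central 80% of the range
  expect_gt(stats::cor(central$x, central$suitability, method = "spearman"), 0.8)
})

test_that("GAM recovers a unimodal niche optimum and a near-linear logit", {
  set.seed(31)
  n1 <- 200; n0 <- 800; n <- n1 + n0
  # species with Gaussian niche at x = 2
  x_bg <- runif(n0 * 8, -3, 7)
  p_acc <- exp(-0.5 * ((x_bg - 2) / 0.8)^2)
  x1 <- sample(x_bg, n1, prob = p_acc)
  dm <- tibble::tibble(
    lon = runif(n), lat = runif(n),
    y = rep(c(1, 0), c(n1, n0)),
    weight = rep(c(n / (2 * n1), n / (2 * n0)), c(n1, n0)),
    x1 = c(x1, runif(n0, -3, 7)),
    x2 = rnorm(n)
  )
  attr(dm, "predictors") <- c("x1", "x2")
  class(dm) <- c("sdm_design", class(dm))
  m <- fit_gam(dm)
  xs <- seq(-3, 7, length.out = 200)
  nd <- tibble::tibble(x1 = xs, x2 = 0)
  resp <- predict(m, nd)
  opt <- xs[which.max(resp)]
  expect_lt(abs(opt - 2), 1)  # within 10% of the 10-unit range
  expect_named(tidy(m), c("term", "edf", "statistic", "p.value"))
  expect_true(all(tidy(m)$edf <= 12))
})

test_that("Maxent shrinks toward a constant as beta grows", {
  dm <- signal_dm(n1 = 80, n0 = 320)
  m1 <- fit_maxent(dm, list(beta_multiplier = 1))
  m_huge <- fit_maxent(dm, list(beta_multiplier = 1e6))
  expect_lt(sum(abs(m_huge$betas)), sum(abs(m1$betas)))
  p_huge <- predict(m_huge, dm)
  expect_lt(stats::sd(p_huge), stats::sd(predict(m1, dm)))
  expect_lt(diff(range(p_huge)), 0.01)  # essentially constant
})

test_that("Maxent hinge features recover a truncated-linear response breakpoint", {
  set.seed(17)
  n1 <- 250; n0 <- 1000; n <- n1 + n0
  # suitability 0 below x = 1, rising linearly above it
  x_cand <- runif(n1 * 20, -2, 4)
  acc <- pmax(0, pmin((x_cand - 1) / 2, 1))
  x1 <- sample(x_cand, n1, prob = acc + 1e-9)
  dm <- tibble::tibble(
    lon = runif(n), lat = runif(n),
    y = rep(c(1, 0), c(n1, n0)),
    weight = rep(c(n / (2 * n1), n / (2 * n0)), c(n1, n0)),
    x1 = c(x1, runif(n0, -2, 4)),
    x2 = rnorm(n)
  )
  attr(dm, "predictors") <- c("x1", "x2")
  class(dm) <- c("sdm_design", class(dm))
  m <- fit_maxent(dm, list(beta_multiplier = 1))
  xs <- seq(-2, 4, length.out = 121)
  resp <- predict(m, tibble::tibble(x1 = xs, x2 = 0))
  # fitted response should be flat-ish below the breakpoint, rising after;
  # locate the knee as the maximum-gain split of the fitted curve
  below <- mean(resp[xs < 0.5]); above <- mean(resp[xs > 2.5])
  expect_gt(above - below, 0.2)
  expect_lt(stats::sd(resp[xs < 0]), 0.1)
})

test_that("RF respects the depth cap and is seed-reproducible", {
  dm <- signal_dm()
  m <- fit_rf(dm, list(n_trees = 51), seed = 4)
  expect_equal(m$fit$num.trees, 51)
  expect_lte(rf_max_depth(m), 10)
  m2 <- fit_rf(dm, seed = 6)
  m3 <- fit_rf(dm, seed = 6)
  expect_identical(predict(m2, dm), predict(m3, dm))
})

test_that("ensemble weights are normalized AUCs and predictions are convex", {
  dm <- signal_dm()
  m1 <- fit_rf(dm, seed = 1)
  m2 <- fit_gam(dm)
  ens <- build_ensemble(list(RF = m1, GAM = m2), c(0.9, 0.6))
  expect_equal(as.numeric(ens$weights), c(0.6, 0.4))
  expect_equal(sum(ens$weights), 1)
  p1 <- predict(m1, dm); p2 <- predict(m2, dm); pe <- predict(ens, dm)
  expect_equal(pe, 0.6 * p1 + 0.4 * p2, tolerance = 1e-12)
  expect_true(all(pe >= pmin(p1, p2) - 1e-12 & pe <= pmax(p1, p2) + 1e-12))

  # equal AUCs -> arithmetic mean; copies of one model -> that model
  ens_eq <- build_ensemble(list(a = m1, b = m2), c(0.8, 0.8))
  expect_equal(predict(ens_eq, dm), (p1 + p2) / 2, tolerance = 1e-12)
  ens_same <- build_ensemble(list(a = m1, b = m1), c(0.7, 0.9))
  expect_equal(predict(ens_same, dm), p1, tolerance = 1e-12)

  expect_error(build_ensemble(list(m1), 0.9), "at least 2")
  expect_error(build_ensemble(list(m1, m2), 0.9), "one AUC per member")
  expect_error(build_ensemble(list(m1, m2), c(0.9, 1.2)), "in \\(0, 1\\]")
  expect_named(tidy(ens), c("member", "weight", "auc"))
})

test_that("suitability maps honor masks and recover planted structure", {
  dm <- signal_dm(n1 = 100, n0 = 400)
  st <- stack_from_dm(dm)
  st$layers$x1$values[3, 4] <- NA
  m <- fit_rf(dm, seed = 2)
  suit <- predict_suitability(m, st)
  expect_true(is.na(suit$values[3, 4]))
  expect_true(all(suit$values >= 0 & suit$values <= 1, na.rm = TRUE))
  # cells with high x1 (the niche driver) outscore low-x1 cells on average
  hi <- suit$values[st$layers$x1$values > 1.5]
  lo <- suit$values[st$layers$x1$values < 0]
  expect_gt(mean(hi, na.rm = TRUE), mean(lo, na.rm = TRUE))

  # constant stack -> constant map
  cst <- env_stack(list(
    x1 = bgrid(matrix(1, 5, 5), 0, 0, 0.1),
    x2 = bgrid(matrix(0, 5, 5), 0, 0, 0.1),
    x3 = bgrid(matrix(2, 5, 5), 0, 0, 0.1)
  ))
  suit2 <- predict_suitability(m, cst)
  expect_equal(max(suit2$values) - min(suit2$values), 0)

  expect_error(predict_suitability(m, env_stack(list(x1 = cst$layers$x1))), "x2")
})

test_that("response curves span the observed range and flatten for unused variables", {
  dm <- signal_dm()
  st <- stack_from_dm(dm)
  m <- fit_gam(dm)
  rc <- response_curve(m, st, "x2", n_points = 40)
  rng <- range(st$layers$x2$values, na.rm = TRUE)
  expect_equal(range(rc$x), rng)
  expect_equal(nrow(rc), 40)
  expect_error(response_curve(m, st, "nope"), "training variable")

  # a model trained on pure-noise x2/x3 barely responds to them compared to x1
  rc_all <- response_curves(m, st, n_points = 30)
  spans <- tapply(rc_all$suitability, rc_all$variable, function(s) diff(range(s)))
  expect_gt(spans[["x1"]], spans[["x2"]])
})

test_that("permutation contributions sum to 100 and find the only informative variable", {
  dm <- signal_dm(n1 = 120, n0 = 480)
  m <- fit_rf(dm, seed = 3)
  vc <- variable_contribution(m, dm, n_permutations = 3, seed = 1)
  expect_equal(sum(vc$contribution), 100, tolerance = 1e-9)
  expect_equal(vc$variable[which.max(vc$contribution)], "x1")
  expect_gt(max(vc$contribution), 60)

  # two symmetric, equally informative variables get similar shares
  set.seed(8)
  n1 <- 150; n0 <- 600; n <- n1 + n0
  dm2 <- tibble::tibble(
    lon = runif(n), lat = runif(n),
    y = rep(c(1, 0), c(n1, n0)),
    weight = rep(c(n / (2 * n1), n / (2 * n0)), c(n1, n0)),
    a = c(rnorm(n1, 1.5), rnorm(n0)),
    b = c(rnorm(n1, 1.5), rnorm(n0))
  )
  attr(dm2, "predictors") <- c("a", "b")
  class(dm2) <- c("sdm_design", class(dm2))
  m2 <- fit_gam(dm2)
  vc2 <- variable_contribution(m2, dm2, n_permutations = 10, seed = 4)
  expect_lt(abs(vc2$contribution[1] - vc2$contribution[2]), 25)
})
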
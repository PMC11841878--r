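gauss_design <- function(n = 2000, shift = 1, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(n, shift, 1), ncol = 1, dimnames = list(NULL, "z"))
  a <- matrix(rnorm(n, 0, 1), ncol = 1, dimnames = list(NULL, "z"))
  list(used = u, available = a)
}

test_that("feature expansion matches its contracts", {
  d <- gauss_design(500)
  fb <- build_features(d$used, d$available, feature_spec("linear"), rm = 2)
  expect_identical(ncol(fb$used), 1L)
  # linear feature is the standardised covariate
  expect_equal(unname(fb$available[, 1]),
               unname((d$available[, 1] - mean(d$available[, 1])) /
                        sd(d$available[, 1])))
  # three covariates give C(3,2) products
  X <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  fb3 <- build_features(X[1:40, ], X, feature_spec("product"), rm = 2)
  expect_identical(ncol(fb3$used), 3L)
  # forward hinge at knot 0.5 over [0, 1] maps 0.75 to 0.5
  Xu <- matrix(seq(0, 1, length.out = 101), ncol = 1,
               dimnames = list(NULL, "u"))
  def <- canopyhsm:::make_feature_def(Xu, feature_spec("hinge", n_knots = 5))
  F <- canopyhsm:::expand_features(def, matrix(0.75, 1, 1, dimnames = list(NULL, "u")))
  expect_equal(unname(F[1, "hf_u_0.5"]), 0.5)
  # zero-variance covariate dropped with a warning
  Xz <- cbind(X, flat = 1)
  expect_warning(build_features(Xz[1:40, ], Xz, feature_spec("linear"), 2),
                 "zero-variance")
})

test_that("no signal and infinite penalty both zero the coefficients", {
  d <- gauss_design(1500, shift = 0, seed = 2)
  m0 <- maxent_hsm(d$used, d$available,
                   feature_spec(c("linear", "quadratic")), fit_config())
  expect_true(all(abs(m0$beta) < 0.15))
  fb <- build_features(d$used, d$available, feature_spec(c("linear", "quadratic")), 2)
  mR <- fit_maxent(fb$used, fb$available, rep(1e6, 2), fit_config())
  expect_identical(unname(mR$beta), c(0, 0))
  expect_equal(gain(mR, fb$used, features = TRUE), 0)
  expect_equal(unique(predict_logistic(mR, fb$available, features = TRUE)), 0.5)
  expect_equal(unique(round(predict_raw(mR, fb$available, features = TRUE), 15)),
               1 / nrow(fb$available))
})

test_that("a Gaussian mean shift recovers the analytic log-density ratio", {
  d <- gauss_design(10000, shift = 1, seed = 3)
  fb <- build_features(d$used, d$available, feature_spec(c("linear", "quadratic")), 2)
  m <- fit_maxent(fb$used, fb$available, rep(1e-6, 2), fit_config(tol = 1e-9),
                  def = fb$def)
  # true ratio exp(x - 1/2): on the standardised scale the linear
  # coefficient is sd(available), the quadratic one 0
  expect_equal(unname(m$beta[1]), sd(d$available[, 1]), tolerance = 0.1)
  expect_lt(abs(m$beta[2]), 0.1)
})

test_that("the solver optimum matches a refining direct search", {
  set.seed(4)
  n <- 120
  u <- cbind(a = rnorm(n, 0.7), b = rnorm(n, -0.4))
  a <- cbind(a = rnorm(2 * n), b = rnorm(2 * n))
  fb <- build_features(u, a, feature_spec("linear"), rm = 2)
  m <- fit_maxent(fb$used, fb$available, fb$lambda, fit_config(tol = 1e-10),
                  def = fb$def)
  best <- grid_search_objective(fb$used, fb$available, fb$lambda)
  expect_lt(abs(m$objective - best), 1e-3)
})

test_that("the objective trace is monotone and soft-thresholding holds", {
  set.seed(5)
  u <- cbind(z = rnorm(200, 0.5))
  a <- cbind(z = rnorm(800))
  fb <- build_features(u, a, feature_spec(c("linear", "quadratic", "hinge"),
                                          n_knots = 10), rm = 2)
  m <- fit_maxent(fb$used, fb$available, fb$lambda, fit_config(), def = fb$def)
  expect_true(all(diff(m$obj_trace) >= -1e-12))
  # features whose gradient magnitude at beta = 0 is below lambda stay 0
  mu_u <- colMeans(fb$used)
  mu_a <- colMeans(fb$available)
  big_lambda <- abs(mu_u - mu_a) * 2 + 0.05
  m2 <- fit_maxent(fb$used, fb$available, big_lambda, fit_config())
  expect_true(all(m2$beta == 0))
})

test_that("raw predictions normalise over the background and order with eta", {
  set.seed(6)
  u <- cbind(z = rnorm(100, 1))
  a <- cbind(z = rnorm(400))
  m <- maxent_hsm(u, a, feature_spec(c("linear", "quadratic")), fit_config())
  raw <- predict_raw(m, a)
  expect_equal(sum(raw), 1)
  hsi <- predict_logistic(m, a)
  expect_identical(order(raw), order(hsi))
  expect_true(all(hsi >= 0 & hsi <= 1))
})

test_that("gain and AIC arithmetic follow their definitions", {
  expect_equal(aic_value(36.7, -15889.3), 31852.0)
  expect_equal(aic_value(0, 0), 0)
  expect_equal(aic_value(2, -10), 24)
  expect_equal(round(exp(2.5), 1), 12.2)
  # adding an unpenalized informative feature never lowers training gain
  set.seed(7)
  u <- cbind(a = rnorm(150, 1), b = rnorm(150, 0.5))
  a_ <- cbind(a = rnorm(600), b = rnorm(600))
  fb <- build_features(u, a_, feature_spec("linear"), rm = 2)
  m1 <- fit_maxent(fb$used[, 1, drop = FALSE], fb$available[, 1, drop = FALSE],
                   1e-8, fit_config(tol = 1e-9))
  m2 <- fit_maxent(fb$used, fb$available, rep(1e-8, 2), fit_config(tol = 1e-9))
  expect_gte(gain(m2, fb$used, features = TRUE) + 1e-6,
             gain(m1, fb$used[, 1, drop = FALSE], features = TRUE))
})

test_that("bootstrap replicates are reproducible and separate separable data", {
  set.seed(8)
  u <- cbind(z = rnorm(120, 3))
  a <- cbind(z = rnorm(600))
  # near-separated data legitimately runs to the iteration cap
  b1 <- suppressWarnings(bootstrap_fit(u, a, feature_spec(c("linear", "quadratic")),
                                       fit_config(replicates = 10, seed = 9)))
  expect_identical(nrow(b1$stats), 10L)
  b2 <- suppressWarnings(bootstrap_fit(u, a, feature_spec(c("linear", "quadratic")),
                                       fit_config(replicates = 10, seed = 9)))
  expect_equal(b1$stats, b2$stats)
  expect_gt(b1$median[["test_auc"]], 0.95)
  expect_error(bootstrap_fit(u[1:2, , drop = FALSE], a, feature_spec("linear"),
                             fit_config()), "too few")
})

test_that("models round-trip through JSON with identical predictions", {
  set.seed(10)
  u <- cbind(z = rnorm(80, 1), w = rnorm(80))
  a <- cbind(z = rnorm(300), w = rnorm(300))
  m <- maxent_hsm(u, a, feature_spec(c("linear", "quadratic", "hinge"),
                                     n_knots = 6), fit_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict_logistic(m2, a), predict_logistic(m, a))
})
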
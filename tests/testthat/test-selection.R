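lq_spec <- feature_spec(c("linear", "quadratic"), 10)

test_that("correlation screening finds duplicates, V = 1 tables and groups", {
  set.seed(1)
  x <- data.frame(a = rnorm(200))
  x$b <- x$a  # duplicate
  x$c <- rnorm(200)
  rep <- correlation_screen(x)
  expect_equal(rep$r2["a", "b"], 1)
  expect_true(any(vapply(rep$groups, function(g) setequal(g, c("a", "b")), TRUE)))
  # perfectly associated 2x2 table: V = 1
  f1 <- factor(rep(c("x", "y"), each = 20))
  rep2 <- correlation_screen(data.frame(u = f1, v = f1),
                             kinds = "categorical")
  expect_equal(rep2$v["u", "v"], 1)
})

test_that("independent covariates show near-zero correlation", {
  set.seed(2)
  x <- as.data.frame(matrix(rnorm(10000 * 3), ncol = 3))
  rep <- correlation_screen(x)
  off <- rep$r2[upper.tri(rep$r2)]
  expect_true(all(off < 0.01))
  expect_length(rep$groups, 3L)
})

test_that("permutation importance separates signal from noise", {
  set.seed(3)
  sim <- simulate_selection_design(n_used = 200, n_available = 1200, seed = 3)
  cols <- c("density_ge60_5ac", "noise1")
  m <- maxent_hsm(sim$used[, cols], sim$available[, cols], lq_spec,
                  fit_config(seed = 3))
  imp <- permutation_importance(m, sim$used[, cols], sim$available[, cols],
                                n_perm = 10, seed = 4)
  expect_equal(sum(imp), 100)
  expect_gt(imp["density_ge60_5ac"], imp["noise1"])
  # single-covariate model: importance 100
  m1 <- maxent_hsm(sim$used[, "density_ge60_5ac", drop = FALSE],
                   sim$available[, "density_ge60_5ac", drop = FALSE],
                   lq_spec, fit_config(seed = 3))
  imp1 <- permutation_importance(m1, sim$used[, 1, drop = FALSE],
                                 sim$available[, 1, drop = FALSE], seed = 5)
  expect_equal(unname(imp1), 100)
})

test_that("percent contribution is normalised path credit", {
  set.seed(4)
  sim <- simulate_selection_design(n_used = 150, n_available = 900, seed = 4)
  cols <- c("sumht_ge50_5ac", "noise2")
  m <- maxent_hsm(sim$used[, cols], sim$available[, cols], lq_spec,
                  fit_config(seed = 4))
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_gt(pc["sumht_ge50_5ac"], pc["noise2"])
  m_no <- m
  m_no$contrib <- NULL
  expect_error(percent_contribution(m_no), "track")
})

test_that("jackknife gains expose uninformative and redundant covariates", {
  set.seed(5)
  n_a <- 1200
  z <- rnorm(n_a)
  avail <- cbind(signal = z, dup = z + rnorm(n_a, 0, 0.01), noise = rnorm(n_a))
  w <- exp(1.5 * z)
  idx <- sample.int(n_a, 200, replace = TRUE, prob = w)
  used <- avail[idx, ]
  jk <- jackknife_gains(used, avail, lq_spec, fit_config(seed = 5))
  expect_lt(jk$only_gain[jk$covariate == "noise"], 0.1)
  # removing a duplicated informative covariate barely moves the gain
  expect_equal(jk$without_gain[jk$covariate == "dup"],
               jk$full_gain[1], tolerance = 0.05)
})

test_that("uncorrelated-model enumeration follows the group structure", {
  set.seed(6)
  n <- 400
  a <- rnorm(n); c_ <- rnorm(n)
  x <- data.frame(a = a, b = a + rnorm(n, 0, 0.1),
                  c = c_, d = c_ + rnorm(n, 0, 0.1), e = rnorm(n))
  rep <- correlation_screen(x)
  cands <- enumerate_uncorrelated_models(report = rep)
  # two groups of two plus a singleton: four models of three covariates
  expect_length(cands, 4L)
  expect_true(all(vapply(cands, length, 0L) == 3L))
  expect_true(all(vapply(cands, function(cc) "e" %in% cc, TRUE)))
  # no correlated pairs: a single full model
  x2 <- as.data.frame(matrix(rnorm(400 * 3), ncol = 3))
  cands2 <- enumerate_uncorrelated_models(report = correlation_screen(x2))
  expect_length(cands2, 1L)
  expect_length(cands2[[1]], 3L)
})

test_that("bootstrap AIC penalises irrelevant additions and is reproducible", {
  wins <- 0L
  for (s in 1:10) {
    # two informative covariates plus one covariate of pure, independent noise
    set.seed(s + 100)
    n_a <- 800
    avail <- cbind(s1 = rnorm(n_a), s2 = rnorm(n_a), junk = rnorm(n_a))
    idx <- sample.int(n_a, 150, replace = TRUE,
                      prob = exp(0.8 * (avail[, "s1"] + avail[, "s2"])))
    used <- avail[idx, ]
    cmp <- bootstrap_aic_compare(list(c("s1", "s2"), c("s1", "s2", "junk")),
                                 used, avail, lq_spec,
                                 fit_config(replicates = 10, seed = s,
                                            track = FALSE))
    if (setequal(cmp$best, c("s1", "s2"))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
  # identical candidates give identical AIC streams under one seed
  sim <- simulate_selection_design(seed = 7)
  cmp2 <- bootstrap_aic_compare(list(sim$signal, sim$signal),
                                sim$used, sim$available, lq_spec,
                                fit_config(replicates = 5, seed = 9,
                                           track = FALSE))
  expect_equal(unname(cmp2$aic[, 1]), unname(cmp2$aic[, 2]))
})

test_that("the RM sweep emits the full grid with consistent arithmetic", {
  sim <- simulate_selection_design(n_used = 120, n_available = 700, seed = 8)
  sw <- rm_sweep(sim$signal, sim$used, sim$available,
                 spec = lq_spec,
                 config = fit_config(replicates = 5, seed = 8, track = FALSE))
  expect_identical(nrow(sw$table), 9L)
  expect_equal(sw$table$delta_aic[1], 0)
  expect_equal(sw$table$mean_aic,
               2 * sw$table$mean_k - 2 * sw$table$mean_lnL)
  expect_true(sw$best_rm %in% seq(1, 5, 0.5))
})
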
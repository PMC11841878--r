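test_that("identical samples give unit P/E in every defined bin", {
  set.seed(1)
  v <- runif(5000, 0, 0.8)
  curve <- pe_curve(v, v)
  expect_true(all(abs(curve$pe[curve$defined] - 1) < 1e-12))
})

test_that("a uniform shift reproduces the analytic density ratio", {
  set.seed(2)
  used <- runif(1e5, 0.5, 1)
  avail <- runif(1e5, 0, 1)
  curve <- pe_curve(used, avail)
  lo <- curve$defined & curve$center < 0.47
  hi <- curve$defined & curve$center > 0.53 & curve$center < 0.97
  expect_true(all(curve$pe[lo] < 0.1))
  expect_true(all(abs(curve$pe[hi] - 2) < 0.2))
})

test_that("empty-background bins are flagged undefined", {
  used <- c(rep(0.1, 50), rep(0.7, 50))
  avail <- rep(0.1, 1000)  # nothing available near 0.7
  curve <- pe_curve(used, c(avail, runif(200, 0, 0.2)))
  expect_true(any(!curve$defined))
  expect_true(all(is.na(curve$pe[!curve$defined])))
  expect_error(pe_curve(used, rep(0.5, 100)), "degenerate")
})

test_that("the P/E mass balance holds on a sampling-consistent design", {
  # available-mass-weighted mean of P/E is sum(P)/sum(E), near 1 when the
  # used sample is a subset of the available one
  set.seed(3)
  avail <- c(rbeta(20000, 1.2, 3), rbeta(2000, 6, 2))
  used <- sample(avail[avail > 0.4], 1500, replace = TRUE)
  curve <- pe_curve(used, avail)
  d <- curve$defined
  wmean <- sum(curve$p[d]) / sum(curve$e[d])
  expect_equal(wmean, 1, tolerance = 0.05)
})

test_that("smoothing is exact on lines, inert on constants, size-preserving", {
  centers <- seq(0.02, 0.6, by = 0.002)
  flat <- toy_pe_curve(centers, rep(2, length(centers)))
  sf <- smooth_pe(flat)
  expect_equal(sf$smoothed, flat$pe)
  line <- toy_pe_curve(centers, 0.5 + 3 * centers)
  sl <- smooth_pe(line, span = 0.3)
  expect_equal(sl$smoothed, line$pe, tolerance = 1e-10)
  expect_identical(nrow(sl), nrow(line))
  expect_error(smooth_pe(toy_pe_curve(centers[1:5], 1:5)), "10 defined")
})

test_that("the forced break lands at the last sub-unit bin", {
  centers <- seq(0.02, 0.2, by = 0.002)
  pe <- ifelse(centers <= 0.03, 0.5, 1.5)
  expect_equal(forced_unsuitable_break(toy_pe_curve(centers, pe)), 0.03)
  expect_warning(fb <- forced_unsuitable_break(toy_pe_curve(centers, rep(2, length(centers)))),
                 "no bin")
  expect_equal(fb, 0.02)
  expect_warning(fb2 <- forced_unsuitable_break(toy_pe_curve(centers, rep(0.5, length(centers)))),
                 "no selection")
  expect_equal(fb2, max(centers))
})

test_that("breakpoint search recovers noiseless kinks exactly", {
  centers <- seq(0.02, 0.8, by = 0.002)
  y <- 0.5 + 1 * pmax(0, centers - 0.2) + 3 * pmax(0, centers - 0.5)
  bp <- fit_breakpoints(toy_pe_curve(centers, y), k = 2, forced_break = 0.02,
                        max_candidates = 1e9)
  expect_equal(bp$breaks, c(0.2, 0.5))
  expect_lt(bp$sse, 1e-20)
})

test_that("k = 0 reduces to the closed-form least-squares line", {
  centers <- seq(0.05, 0.5, by = 0.01)
  set.seed(4)
  y <- 1 + 2 * centers + rnorm(length(centers), 0, 0.1)
  bp <- fit_breakpoints(toy_pe_curve(centers, y), k = 0, forced_break = 0.05)
  f <- stats::lm(y ~ centers)
  expect_equal(bp$sse, sum(stats::residuals(f)^2))
})

test_that("the exhaustive search matches an independent brute force on 30 bins", {
  centers <- seq(0.1, 0.68, by = 0.02)  # 30 bins
  set.seed(5)
  y <- 1 + pmax(0, centers - 0.3) * 4 + rnorm(30, 0, 0.05)
  bp <- fit_breakpoints(toy_pe_curve(centers, y), k = 1, forced_break = 0.1,
                        max_candidates = 1e9)
  cand <- centers[centers > 0.1 & centers < max(centers)]
  oracle <- brute_breakpoint_search(centers, y, cand, 1)
  expect_equal(bp$breaks, oracle$breaks)
  expect_equal(bp$sse, oracle$sse, tolerance = 1e-10)
})

test_that("noisy kinks are recovered within one grid step in most seeds", {
  centers <- seq(0.02, 0.8, by = 0.01)
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    y <- 0.5 + 6 * pmax(0, centers - 0.3) + 12 * pmax(0, centers - 0.6) +
      rnorm(length(centers), 0, 0.1)
    bp <- fit_breakpoints(toy_pe_curve(centers, y), k = 2, forced_break = 0.02,
                          max_candidates = 1e9)
    if (all(abs(sort(bp$breaks) - c(0.3, 0.6)) <= 0.0100001)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("class assembly reproduces the five-class scheme and merges", {
  cls <- build_classes(0.03, c(0.19, 0.34, 0.57), max_hsi = 0.78)
  expect_equal(cls$boundaries, c(0.03, 0.19, 0.34, 0.57, 0.78))
  expect_equal(cls$labels, c("unsuitable", "marginal", "low", "medium", "high"))
  # the post-hoc removal of anomalous breakpoints is an explicit merge
  cls2 <- build_classes(0.03, c(0.19, 0.27, 0.34, 0.57, 0.69), max_hsi = 0.78,
                        merges = c(0.27, 0.69))
  expect_equal(cls2$boundaries, cls$boundaries)
  expect_error(build_classes(0.03, c(0.19), 0.78, merges = 0.5), "not in the fit")
  expect_error(build_classes(0.03, c(0.19), 0.78, labels = c("a", "b")),
               "mismatch")
  cls3 <- build_classes(0.03, numeric(0), 0.78)
  expect_length(cls3$labels, 2L)
})

test_that("classification uses left-closed intervals with a closed top", {
  cls <- build_classes(0.03, c(0.19, 0.34, 0.57), max_hsi = 0.78)
  expect_equal(cls$labels[classify_hsi(c(0.10, 0.19, 0.78, 0.0), cls) + 1L],
               c("marginal", "low", "high", "unsuitable"))
  expect_warning(code <- classify_hsi(0.9, cls), "clamped")
  expect_equal(code, 4L)
  expect_error(classify_hsi(-0.1, cls), "negative")
  # monotone: higher HSI never maps to a lower class
  set.seed(6)
  v <- sort(runif(200, 0, 0.78))
  expect_true(all(diff(classify_hsi(v, cls)) >= 0))
  r <- grid_raster(matrix(c(0.01, 0.2, 0.4, 0.6), 2, 2))
  cr <- classify_grid(r, cls)
  expect_equal(cr$values, matrix(c(0, 2, 3, 4), 2, 2))
})
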
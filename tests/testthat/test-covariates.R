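test_that("window radii match the 1- and 5-acre design constants", {
  expect_equal(round(circle_radius_for_area(1), 2), 35.89)
  expect_equal(round(circle_radius_for_area(5), 2), 80.25)
  expect_equal(circle_radius_for_area(0), 0)
  expect_error(circle_radius_for_area(-1), ">= 0")
})

test_that("window statistics match hand-derived cases", {
  g <- grid_spec(0, 0, 1, 1, res = 5)
  # 5 TAOs of 65 m within the 5-acre radius of the single cell centre
  taos <- canopyhsm:::tao_set(data.frame(x = c(2.5, 30, 60, 2.5, 40),
                                         y = c(2.5, 2.5, 2.5, 70, 40),
                                         height_m = rep(65, 5)))
  lay <- tao_window_stat(taos, g, "count_density", height_min = 60, window_area = 5)
  expect_equal(lay$values[1, 1], 1.0)  # 5 trees / 5 acres
  # heights {50, 60}: sum 110, sample sd 7.0711
  t2 <- canopyhsm:::tao_set(data.frame(x = c(1, 2), y = c(1, 2),
                                       height_m = c(50, 60)))
  expect_equal(tao_window_stat(t2, g, "sum", 50, 5)$values[1, 1], 110)
  expect_equal(round(tao_window_stat(t2, g, "sd", 50, 5)$values[1, 1], 4), 7.0711)
  # empty window: density 0, sd 0, min/mean/max 0
  t0 <- canopyhsm:::empty_tao_set()
  for (st in c("count_density", "sum", "sd", "min", "mean", "max")) {
    expect_equal(tao_window_stat(t0, g, st, 50, 5)$values[1, 1], 0)
  }
})

test_that("scatter implementation equals the brute-force scan exactly", {
  set.seed(7)
  taos <- canopyhsm:::tao_set(data.frame(x = runif(50, 0, 100),
                                         y = runif(50, 0, 100),
                                         height_m = runif(50, 30, 100)))
  g <- grid_spec(0, 0, 20, 20, res = 5)
  for (st in c("count_density", "sum", "sd", "min", "mean", "max")) {
    for (wa in c(1, 5)) {
      lay <- tao_window_stat(taos, g, st, height_min = 50, window_area = wa)
      expect_equal(lay$values, brute_window_stat(taos, g, st, 50, wa),
                   tolerance = 1e-10)
    }
  }
})

test_that("raising the height threshold never raises density, sum or count", {
  set.seed(8)
  taos <- canopyhsm:::tao_set(data.frame(x = runif(80, 0, 100),
                                         y = runif(80, 0, 100),
                                         height_m = runif(80, 20, 110)))
  g <- grid_spec(0, 0, 10, 10, res = 10)
  for (st in c("count_density", "sum")) {
    lo <- tao_window_stat(taos, g, st, height_min = 40, window_area = 5)
    hi <- tao_window_stat(taos, g, st, height_min = 60, window_area = 5)
    expect_true(all(hi$values <= lo$values + 1e-12))
  }
})

test_that("1-acre counts nest inside concentric 5-acre counts", {
  set.seed(9)
  taos <- canopyhsm:::tao_set(data.frame(x = runif(60, 0, 150),
                                         y = runif(60, 0, 150),
                                         height_m = runif(60, 50, 100)))
  g <- grid_spec(0, 0, 6, 6, res = 25)
  c1 <- tao_window_stat(taos, g, "count_density", 50, 1)$values * 1
  c5 <- tao_window_stat(taos, g, "count_density", 50, 5)$values * 5
  expect_true(all(c1 <= c5 + 1e-12))
})

test_that("density is additive over disjoint TAO subsets", {
  set.seed(10)
  df <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100),
                   height_m = runif(40, 50, 100))
  g <- grid_spec(0, 0, 8, 8, res = 12.5)
  all_ <- tao_window_stat(canopyhsm:::tao_set(df), g, "count_density", 50, 5)
  a <- tao_window_stat(canopyhsm:::tao_set(df[1:15, ]), g, "count_density", 50, 5)
  b <- tao_window_stat(canopyhsm:::tao_set(df[16:40, ]), g, "count_density", 50, 5)
  expect_equal(a$values + b$values, all_$values)
})

test_that("stack assembly enforces grid alignment and presets name the trio", {
  g <- grid_spec(0, 0, 4, 4, res = 5)
  taos <- canopyhsm:::tao_set(data.frame(x = 10, y = 10, height_m = 70))
  st <- final3_stack(taos, g)
  expect_named(st$layers, c("density_ge60_5ac", "sumht_ge50_5ac", "sdht_ge50_5ac"))
  shifted <- st$layers[[1]]
  shifted$xmin <- shifted$xmin + 1
  expect_error(assemble_stack(st$layers[[1]], shifted), "same grid")
})

test_that("rasters and stacks round-trip through ASCII-grid files", {
  v <- matrix(c(0, 1.5, -2.25, 4096.125, 0.1, 7), 2, 3)
  r <- grid_raster(v, xmin = 10, ymin = 20, res = 5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(r, path)
  back <- read_asc(path)
  expect_equal(back$values, v, tolerance = 1e-9)
  expect_equal(back$xmin, 10)
  expect_equal(back$res, 5)
  dir <- withr::local_tempdir()
  taos <- canopyhsm:::tao_set(data.frame(x = c(10, 15), y = c(10, 12),
                                         height_m = c(70, 55)))
  st <- final3_stack(taos, grid_spec(0, 0, 5, 5, res = 5))
  write_stack(st, dir)
  st2 <- read_stack(dir)
  expect_named(st2$layers, names(st$layers))
  for (nm in names(st$layers)) {
    expect_equal(st2$layers[[nm]]$values, st$layers[[nm]]$values,
                 tolerance = 1e-9)
  }
})
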
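class_raster_from <- function(codes, res = 5, labels = c("unsuitable", "low")) {
  r <- grid_raster(codes, 0, 0, res = res)
  attr(r, "classes") <- structure(list(boundaries = seq_along(labels) * 0.2,
                                       labels = labels),
                                  class = "habitat_classes")
  r
}

test_that("habitat masks polygonize qualifying cells with 4-connectivity", {
  expect_length(habitat_mask(class_raster_from(matrix(0L, 4, 4)), "low"), 0L)
  one <- matrix(0L, 4, 4)
  one[2, 3] <- 1L
  m1 <- habitat_mask(class_raster_from(one), "low")
  expect_length(m1, 1L)
  expect_equal(polygon_area(m1[[1]]), 25)
  diagonal <- matrix(0L, 4, 4)
  diagonal[2, 2] <- 1L
  diagonal[3, 3] <- 1L
  expect_length(habitat_mask(class_raster_from(diagonal), "low"), 2L)
  blob <- matrix(0L, 5, 5)
  blob[2:4, 2:4] <- 1L
  mb <- habitat_mask(class_raster_from(blob), "low")
  expect_length(mb, 1L)
  expect_equal(polygon_area(mb[[1]]), 9 * 25)
})

test_that("buffer grouping collects tall TAOs and dissolves nearby masks", {
  masks <- list(rect_polygon(0, 0, 50, 50), rect_polygon(150, 0, 200, 50))
  taos <- canopyhsm:::tao_set(data.frame(
    x = c(110, 25, 25, 300),
    y = c(25, 25, 25, 300),
    height_m = c(70, 45, 80, 90)))
  # masks 100 m apart: buffers (80.25 each) overlap -> one merged group
  g <- buffer_and_collect(masks, taos, buffer = 80.25, tao_min_height = 50)
  expect_length(g, 1L)
  # 70-m TAO 60 m outside a mask is included; the 45-m TAO inside is not;
  # the distant 90-m TAO is outside every buffer
  expect_equal(sort(g[[1]]$taos$height_m), c(70, 80))
  # with a tiny buffer the masks stay separate
  g2 <- buffer_and_collect(masks, taos, buffer = 10, tao_min_height = 50)
  expect_length(g2, 2L)
})

test_that("concave hulls honour their contracts", {
  tri <- cbind(c(0, 4, 1), c(0, 0, 3))
  h <- concave_hull(tri)
  expect_equal(polygon_area(h), polygon_area(tri))
  # convex-hull oracle at very large concavity
  set.seed(1)
  pts <- cbind(runif(60), runif(60))
  hc <- concave_hull(pts, concavity = 1e6)
  cvx <- pts[rev(grDevices::chull(pts)), ]
  expect_equal(polygon_area(hc), polygon_area(cvx))
  # C-shaped cloud: tighter than convex, still contains every point
  th <- seq(0, 1.5 * pi, length.out = 80)
  set.seed(2)
  cpts <- cbind(cos(th), sin(th)) + matrix(rnorm(160, 0, 0.02), ncol = 2)
  hcc <- concave_hull(cpts, 0.8)
  expect_lt(polygon_area(hcc), polygon_area(cpts[rev(grDevices::chull(cpts)), ]))
  expect_true(all(canopyhsm:::polygon_region_distance(cpts[, 1], cpts[, 2], hcc) < 1e-9))
  expect_warning(expect_null(concave_hull(cbind(c(0, 1), c(0, 1)))), "fewer")
  expect_warning(expect_null(concave_hull(cbind(0:3, 0:3))), "collinear")
})

test_that("perimeter smoothing is a closing plus a 5-m dilation", {
  p <- rect_polygon(0, 0, 100, 80)
  sp <- smooth_perimeter(p, 60, 55, resolution = 1)
  # convex input: closing is the identity, so the result is the exact 5-m
  # dilation, whose area follows the Steiner formula
  steiner <- 100 * 80 + 2 * (100 + 80) * 5 + pi * 25
  expect_equal(polygon_area(sp), steiner, tolerance = 0.01)
  expect_true(all(points_in_polygon(p[, 1], p[, 2], sp)))
  # every output vertex sits ~5 m from the input region
  dv <- canopyhsm:::polygon_region_distance(sp[, 1], sp[, 2], p)
  expect_true(all(abs(dv - 5) < 2.5))
  expect_null(smooth_perimeter(NULL))
})

test_that("closing removes narrow bays", {
  # U-shape with a 40-m-wide bay: closing radius 55 > half-width fills it
  bay <- cbind(c(0, 200, 200, 120, 120, 80, 80, 0),
               c(0, 0, 100, 100, 30, 30, 100, 100))
  sp <- smooth_perimeter(bay, 60, 55, resolution = 2)
  centre_bay <- points_in_polygon(100, 80, sp)  # point inside the old bay
  expect_true(centre_bay)
  expect_true(all(points_in_polygon(bay[, 1], bay[, 2], sp)))
})

test_that("the containment chain TAOs in hull in smoothed polygon holds", {
  set.seed(3)
  pts <- cbind(runif(40, 0, 120), runif(40, 0, 90))
  hull <- concave_hull(pts, 0.8)
  sp <- smooth_perimeter(hull, 60, 55, resolution = 2)
  expect_true(all(canopyhsm:::polygon_region_distance(pts[, 1], pts[, 2], hull) < 1e-9))
  expect_true(all(points_in_polygon(hull[, 1], hull[, 2], sp)))
})

test_that("patch summaries aggregate HSI, classes and status", {
  hsi <- grid_raster(matrix(c(0.2, 0.4, 0.1, 0.3), 2, 2), 0, 0, res = 10)
  codes <- grid_raster(matrix(c(1L, 1L, 0L, 1L), 2, 2), 0, 0, res = 10)
  attr(codes, "classes") <- structure(list(boundaries = c(0.15, 0.5),
                                           labels = c("unsuitable", "low")),
                                      class = "habitat_classes")
  patch <- list(list(polygon = rect_polygon(0, 0, 10, 20),  # covers column 1
                     hull = rect_polygon(1, 1, 9, 19),
                     taos = data.frame(x = 5, y = 5, height_m = 60)))
  ps <- summarize_patches(patch, hsi, codes, used_polygons = list())
  expect_equal(ps$mean_hsi, 0.3)
  expect_equal(ps$median_hsi, 0.3)
  expect_equal(ps$max_hsi, 0.4)
  expect_equal(ps$status, "available")
  # class-area breakdown conserves the covered-cell area
  expect_equal(ps$class_ha_unsuitable + ps$class_ha_low, 2 * 100 / 1e4)
  ps2 <- summarize_patches(patch, hsi, codes,
                           used_polygons = list(rect_polygon(5, 5, 8, 8)))
  expect_equal(ps2$status, "used")
})

test_that("degenerate buffer groups are dropped with a warning", {
  codes <- matrix(0L, 10, 10)
  codes[5, 5] <- 1L
  cr <- class_raster_from(codes)
  taos <- canopyhsm:::tao_set(data.frame(x = c(22, 28), y = c(22, 28),
                                         height_m = c(60, 70)))
  expect_warning(p <- delineate_patches(cr, taos), "too few")
  expect_length(p, 0L)
})
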
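# Moving-window TAO statistics on the analysis grid.  The final model's
# covariate trio -- density of TAOs >= 60 m and the sum and standard
# deviation of heights of TAOs >= 50 m, all in 5-acre circular windows on a
# 5-m grid -- is available as the `final3` preset; the general family
# (min/mean/max/sum/sd/density by height class and window area) is exposed
# through `tao_window_stat()`.

#' Radius of a circle with a given area in acres
#'
#' `pi * r^2 = area * 4046.8564224`.  The two window sizes used throughout
#' the analysis are 1 acre (35.89 m) and 5 acres (80.25 m).
#'
#' @param area area in acres (>= 0).
#' @return radius in metres.
#' @export
circle_radius_for_area <- function(area) {
  if (any(area < 0)) stop("`area` must be >= 0")
  sqrt(area * ACRE_M2 / pi)
}

#' Analysis grid specification
#'
#' @param xmin,ymin lower-left corner (m).
#' @param nrow,ncol grid dimensions (rows south to north).
#' @param res cell size in metres (default 5, the analysis resolution).
#' @param crs CRS tag.
#' @export
grid_spec <- function(xmin, ymin, nrow, ncol, res = 5, crs = "local-metres") {
  if (res <= 0) stop("cell size must be positive")
  structure(list(xmin = unname(xmin), ymin = unname(ymin),
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 res = unname(res), crs = crs),
            class = "grid_spec")
}

#' Derive a grid spec covering a raster's extent
#' @param r a [grid_raster()].
#' @param res target cell size (m).
#' @export
grid_spec_from_raster <- function(r, res = 5) {
  ext <- raster_extent(r)
  grid_spec(ext["xmin"], ext["ymin"],
            nrow = ceiling((ext["ymax"] - ext["ymin"]) / res),
            ncol = ceiling((ext["xmax"] - ext["xmin"]) / res),
            res = res, crs = r$crs)
}

grid_blank <- function(grid, fill = 0) {
  grid_raster(matrix(fill, grid$nrow, grid$ncol), xmin = grid$xmin,
              ymin = grid$ymin, res = grid$res, crs = grid$crs)
}

#' Circular moving-window TAO statistic
#'
#' For every grid cell, collects the TAOs with `height_m >= height_min`
#' whose distance from the cell centre is at most the window radius
#' (inclusive) and computes the requested statistic:
#' \describe{
#'   \item{count_density}{count divided by the window area, in stems per
#'     acre regardless of window size.}
#'   \item{sum}{sum of heights (m); 0 for an empty window.}
#'   \item{sd}{sample (n-1) standard deviation of heights (m); 0 when the
#'     window holds fewer than two TAOs.}
#'   \item{min,mean,max}{of heights (m); 0 for an empty window.}
#' }
#'
#' The implementation scatters each TAO into the precomputed disc of cells
#' it reaches, accumulating count, sum, sum of squares, min and max; this
#' is exactly equivalent to a per-cell scan over all TAOs (the brute-force
#' form used as a test oracle) but costs O(TAOs x window cells).
#'
#' @param taos a `tao_set`.
#' @param grid a [grid_spec()].
#' @param stat one of `"count_density"`, `"sum"`, `"sd"`, `"min"`,
#'   `"mean"`, `"max"`.
#' @param height_min height threshold in metres (default 50).
#' @param window_area window size in acres (default 5).
#' @return a [grid_raster()] layer named `<stat>_ge<height_min>_<area>ac`.
#' @export
tao_window_stat <- function(taos, grid,
                            stat = c("count_density", "sum", "sd", "min",
                                     "mean", "max"),
                            height_min = 50, window_area = 5) {
  stat <- match.arg(stat)
  stopifnot(inherits(grid, "grid_spec"))
  if (window_area <= 0) stop("`window_area` must be positive")
  src <- attr(taos, "source")
  if (!is.null(src) && !is.null(src$crs) && !is.na(src$crs) &&
      !identical(src$crs, grid$crs)) {
    stop("TAO set and grid have different CRS tags")
  }
  r <- circle_radius_for_area(window_area)
  sel <- taos$height_m >= height_min
  acc <- tao_window_accumulate(taos$x[sel], taos$y[sel], taos$height_m[sel],
                               grid, r)
  v <- switch(stat,
    count_density = acc$cnt / window_area,
    sum = acc$s1,
    mean = ifelse(acc$cnt > 0, acc$s1 / acc$cnt, 0),
    sd = {
      s <- matrix(0, grid$nrow, grid$ncol)
      ok <- acc$cnt >= 2
      s[ok] <- sqrt(pmax(0, (acc$s2[ok] - acc$s1[ok]^2 / acc$cnt[ok]) /
                            (acc$cnt[ok] - 1)))
      s
    },
    min = ifelse(is.finite(acc$mn), acc$mn, 0),
    max = ifelse(is.finite(acc$mx), acc$mx, 0))
  out <- grid_blank(grid)
  out$values <- v
  out$name <- sprintf("%s_ge%g_%gac",
                      if (stat == "count_density") "density" else
                        if (stat %in% c("sum", "sd", "min", "mean", "max"))
                          paste0(stat, "ht") else stat,
                      height_min, window_area)
  out
}

tao_window_accumulate <- function(tx, ty, th, grid, radius) {
  nr <- grid$nrow; nc <- grid$ncol; res <- grid$res
  cnt <- matrix(0, nr, nc); s1 <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
  mx <- matrix(-Inf, nr, nc); mn <- matrix(Inf, nr, nc)
  if (length(tx)) {
    xc <- grid$xmin + (seq_len(nc) - 0.5) * res
    yc <- grid$ymin + (seq_len(nr) - 0.5) * res
    for (k in seq_along(tx)) {
      jlo <- max(1L, ceiling((tx[k] - radius - grid$xmin) / res + 0.5))
      jhi <- min(nc, floor((tx[k] + radius - grid$xmin) / res + 0.5))
      ilo <- max(1L, ceiling((ty[k] - radius - grid$ymin) / res + 0.5))
      ihi <- min(nr, floor((ty[k] + radius - grid$ymin) / res + 0.5))
      if (jlo > jhi || ilo > ihi) next
      d2 <- outer((yc[ilo:ihi] - ty[k])^2, (xc[jlo:jhi] - tx[k])^2, `+`)
      m <- d2 <= radius^2  # inclusive: TAOs exactly on the rim count
      if (!any(m)) next
      ri <- ilo:ihi; ci <- jlo:jhi
      cnt[ri, ci] <- cnt[ri, ci] + m
      s1[ri, ci] <- s1[ri, ci] + m * th[k]
      s2[ri, ci] <- s2[ri, ci] + m * th[k]^2
      mx[ri, ci] <- pmax(mx[ri, ci], ifelse(m, th[k], -Inf))
      mn[ri, ci] <- pmin(mn[ri, ci], ifelse(m, th[k], Inf))
    }
  }
  list(cnt = cnt, s1 = s1, s2 = s2, mx = mx, mn = mn)
}

#' Assemble aligned layers into a covariate stack
#'
#' @param ... named [grid_raster()] layers on an identical grid (names
#'   default to each layer's own `name`).
#' @return a `covariate_stack`.
#' @export
assemble_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) &&
      !inherits(layers[[1L]], "grid_raster")) {
    layers <- layers[[1L]]
  }
  if (!length(layers)) stop("no layers supplied")
  nms <- names(layers)
  if (is.null(nms)) nms <- rep("", length(layers))
  nms <- ifelse(nms == "", vapply(layers, function(l) l$name, ""), nms)
  for (l in layers[-1L]) {
    if (!same_grid(layers[[1L]], l)) stop("layers are not on the same grid")
  }
  names(layers) <- nms
  structure(list(layers = layers,
                 grid = grid_spec(layers[[1L]]$xmin, layers[[1L]]$ymin,
                                  nrow(layers[[1L]]$values),
                                  ncol(layers[[1L]]$values),
                                  layers[[1L]]$res, layers[[1L]]$crs)),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate_stack: %d layers on %d x %d @ %g m grid\n",
              length(x$layers), x$grid$nrow, x$grid$ncol, x$grid$res))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Final-model covariate preset
#'
#' Computes the three covariates of the final habitat model: per-acre
#' density of TAOs >= 60 m, sum of heights of TAOs >= 50 m, and standard
#' deviation of heights of TAOs >= 50 m, each over 5-acre circular windows.
#'
#' @param taos a `tao_set`.
#' @param grid a [grid_spec()] (5-m analysis grid).
#' @return a `covariate_stack` with layers `density_ge60_5ac`,
#'   `sumht_ge50_5ac`, `sdht_ge50_5ac`.
#' @export
final3_stack <- function(taos, grid) {
  assemble_stack(
    tao_window_stat(taos, grid, "count_density", height_min = 60, window_area = 5),
    tao_window_stat(taos, grid, "sum", height_min = 50, window_area = 5),
    tao_window_stat(taos, grid, "sd", height_min = 50, window_area = 5))
}

#' Write / read a covariate stack
#'
#' One ESRI ASCII grid per layer plus a JSON manifest, all in `dir`.
#' @param stack a `covariate_stack`.
#' @param dir output directory (created if needed).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_asc(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  jsonlite::write_json(list(layers = names(stack$layers), crs = stack$grid$crs),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- lapply(meta$layers, function(nm) {
    read_asc(file.path(dir, paste0(nm, ".asc")), crs = meta$crs, name = nm)
  })
  names(layers) <- meta$layers
  assemble_stack(layers)
}
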
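# Balanced acceptance sampling (BAS): a random-start 2-D Halton sequence
# (bases 2 and 3) scaled to the region's bounding box, with points accepted
# when they fall inside the region.  Used/available labelling applies the
# 20-m inner-boundary exclusion; every accepted point stays in the
# "available" pool whatever its label.

halton_radical_inverse <- function(i, base) {
  out <- numeric(length(i))
  f <- 1 / base
  i <- as.numeric(i)
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

#' Draw a balanced acceptance sample over a region
#'
#' Generates the Halton sequence in bases 2 and 3 starting at random
#' per-base integer index offsets (each uniform on \[0, 10^7), derived from
#' `seed`), scales each Halton point to the region's bounding box, accepts
#' points falling inside the region, and stops after `n` acceptances.
#' Sequence order is retained, so any prefix of the sample is itself
#' spatially balanced.
#'
#' @param region a polygon matrix or list of polygons (union taken).
#' @param n number of points to accept (>= 1).
#' @param seed integer seed for the random start.
#' @return data.frame with columns `x`, `y` and attributes `offsets`
#'   (the Halton index offsets) and `seed`.
#' @export
bas_points <- function(region, n, seed = 1L) {
  if (is.matrix(region)) region <- list(region)
  region <- lapply(region, as_polygon)
  if (n < 1) stop("`n` must be >= 1")
  total_area <- sum(vapply(region, polygon_area, 0))
  if (total_area <= 0) stop("degenerate region")
  bb <- apply(do.call(rbind, region), 2L, range)
  offsets <- with_seed(seed, floor(stats::runif(2L, 0, 1e7)))
  xs <- numeric(0); ys <- numeric(0)
  start <- 1
  # acceptance rate ~ region area / bbox area; draw in growing chunks
  rate <- max(total_area / ((bb[2, 1] - bb[1, 1]) * (bb[2, 2] - bb[1, 2])), 1e-3)
  while (length(xs) < n) {
    m <- ceiling((n - length(xs)) / rate * 1.2) + 16
    idx <- seq(start, start + m - 1)
    u <- halton_radical_inverse(idx + offsets[1L], 2L)
    v <- halton_radical_inverse(idx + offsets[2L], 3L)
    px <- bb[1L, 1L] + u * (bb[2L, 1L] - bb[1L, 1L])
    py <- bb[1L, 2L] + v * (bb[2L, 2L] - bb[1L, 2L])
    inside <- rep(FALSE, m)
    for (p in region) inside <- inside | points_in_polygon(px, py, p)
    xs <- c(xs, px[inside]); ys <- c(ys, py[inside])
    start <- start + m
  }
  out <- data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
  attr(out, "offsets") <- offsets
  attr(out, "seed") <- seed
  out
}

#' Sample size for a target point density
#'
#' @param region_area region area in hectares.
#' @param ha_per_point target hectares per sample point (the study design's
#'   density was one point per 2.02 ha).
#' @return `round(region_area / ha_per_point)`.
#' @export
target_n_for_density <- function(region_area, ha_per_point) {
  if (region_area <= 0 || ha_per_point <= 0) {
    stop("`region_area` and `ha_per_point` must be positive")
  }
  round(region_area / ha_per_point)
}

#' Label sample points used/available
#'
#' A point is labelled `used` when it lies inside a used polygon *and* its
#' distance to that polygon's boundary is at least `exclusion` metres
#' (inclusive at the boundary of the exclusion rule).  All points -- used or
#' not -- remain in the available pool, matching the two-sample design in
#' which the used sample is a subset of the available sample.
#'
#' @param points data.frame with `x`, `y` (e.g. from [bas_points()]).
#' @param used_polygons list of polygons of occupied habitat.
#' @param exclusion inner-boundary exclusion distance in metres (default 20).
#' @return a `labeled_sample`: the points with a `label` factor
#'   (`used`/`available`) and design metadata attributes.
#' @export
label_samples <- function(points, used_polygons, exclusion = 20) {
  if (exclusion < 0) stop("`exclusion` must be >= 0")
  if (is.matrix(used_polygons)) used_polygons <- list(used_polygons)
  used_polygons <- lapply(used_polygons, as_polygon)
  used <- rep(FALSE, nrow(points))
  for (p in used_polygons) {
    inside <- points_in_polygon(points$x, points$y, p)
    if (any(inside)) {
      d <- polygon_boundary_distance(points$x[inside], points$y[inside], p)
      used[inside] <- used[inside] | (d >= exclusion)
    }
  }
  out <- data.frame(x = points$x, y = points$y,
                    label = factor(ifelse(used, "used", "available"),
                                   levels = c("used", "available")))
  attr(out, "exclusion") <- exclusion
  attr(out, "seed") <- attr(points, "seed")
  attr(out, "offsets") <- attr(points, "offsets")
  class(out) <- c("labeled_sample", "data.frame")
  out
}

#' Extract used / available design matrices from a covariate stack
#'
#' Covariate vectors are read by nearest-cell lookup with the half-open
#' cell convention `[x0, x0 + res)`; row order follows sample order.  The
#' available matrix holds *all* points (the used points are a subset).
#'
#' @param sample a `labeled_sample`.
#' @param stack a `covariate_stack`.
#' @return list with elements `used` and `available` (matrices with one
#'   column per layer) and `points` (the sample with covariate columns
#'   appended).
#' @export
extract_design <- function(sample, stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  first <- stack$layers[[1L]]
  idx <- cell_index(first, sample$x, sample$y)
  if (any(idx[, "inside"] == 0)) {
    bad <- which(idx[, "inside"] == 0)
    stop(sprintf("points outside the stack extent (rows %s)",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  av <- vapply(stack$layers,
               function(l) l$values[cbind(idx[, "row"], idx[, "col"])],
               numeric(nrow(sample)))
  av <- matrix(av, nrow = nrow(sample),
               dimnames = list(NULL, names(stack$layers)))
  pts <- cbind(as.data.frame(sample), as.data.frame(av))
  attr(pts, "exclusion") <- attr(sample, "exclusion")
  attr(pts, "seed") <- attr(sample, "seed")
  attr(pts, "offsets") <- attr(sample, "offsets")
  list(used = av[sample$label == "used", , drop = FALSE],
       available = av,
       points = pts)
}

#' Write a labelled sample (with covariates) to CSV + JSON sidecar
#' @param design result of [extract_design()] (or a `labeled_sample`).
#' @param path CSV path; design metadata goes to `<path>.json`.
#' @export
write_sample <- function(design, path) {
  pts <- if (is.list(design) && !is.null(design$points)) design$points else
    as.data.frame(design)
  utils::write.csv(pts, path, row.names = FALSE)
  meta <- list(exclusion_m = attr(design$points %||% design, "exclusion"),
               seed = attr(design$points %||% design, "seed"),
               halton_offsets = attr(design$points %||% design, "offsets"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
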
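# Synthetic forest landscapes: a second-growth matrix with embedded
# old-growth patches of tall (>= 60 m) trees.  Used polygons coincide with
# the old-growth patches, mirroring the occupied-stand design the habitat
# model assumes.  Ground is flat zero; no terrain or LiDAR noise is
# simulated.

#' Height distribution specification
#'
#' A small declarative spec for tree-height distributions used by
#' [forest_scenario()].  Supported families: `"lognormal"` (`meanlog`,
#' `sdlog`), `"normal"` (`mean`, `sd`, truncated at > 0), `"uniform"`
#' (`min`, `max`) and `"weibull"` (`shape`, `scale`).
#'
#' @param family distribution family name.
#' @param ... family parameters (see above).
#' @export
height_dist <- function(family = c("lognormal", "normal", "uniform", "weibull"), ...) {
  family <- match.arg(family)
  structure(list(family = family, params = list(...)), class = "height_dist")
}

sample_heights <- function(dist, n) {
  p <- dist$params
  h <- switch(dist$family,
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    normal    = stats::rnorm(n, p$mean, p$sd),
    uniform   = stats::runif(n, p$min, p$max),
    weibull   = stats::rweibull(n, p$shape, p$scale))
  # heights must be positive; redraw the (rare) non-positive normal draws
  bad <- which(h <= 0)
  while (length(bad)) {
    h[bad] <- sample_heights(dist, length(bad))
    bad <- which(h <= 0)
  }
  h
}

dist_upper_support <- function(dist) {
  p <- dist$params
  switch(dist$family,
         uniform = p$max,
         Inf)
}

#' Define a synthetic forest scenario
#'
#' A scenario is a rectangular extent filled with a second-growth matrix
#' (homogeneous Poisson stem placement, heights mostly below 50 m) plus a
#' set of old-growth patch polygons, each carrying an extra Poisson layer
#' of tall trees (heights in \[50, 120\] m, up to roughly 25 stems/ha of
#' trees 60 m and taller).  The patch polygons double as the "used"
#' (occupied) habitat polygons for sampling.
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param matrix_height_dist a [height_dist()] for matrix tree heights.
#' @param matrix_stem_density matrix stems per hectare (>= 0).
#' @param patches list of patches, each
#'   `list(polygon =, tall_tree_density =, tall_height_dist =)`; densities
#'   in stems/ha, polygons inside the extent.
#' @param crown_radius_coeff crown radius per metre of tree height
#'   (dimensionless, default 0.1).
#' @param cluster_prob probability that a stem carries a second leader
#'   within `cluster_radius` metres (redwood stump-sprout clumping);
#'   0 (off) by default.
#' @param cluster_radius leader offset radius in metres (default 1).
#' @param seed integer seed making the scenario fully reproducible.
#' @return an object of class `forest_scenario`.
#' @export
forest_scenario <- function(extent,
                            matrix_height_dist = height_dist("lognormal",
                                                             meanlog = log(28),
                                                             sdlog = 0.22),
                            matrix_stem_density = 150,
                            patches = list(),
                            crown_radius_coeff = 0.1,
                            cluster_prob = 0,
                            cluster_radius = 1,
                            seed = 1L) {
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[3L] <= extent[1L] || extent[4L] <= extent[2L]) {
    stop("`extent` must be c(xmin, ymin, xmax, ymax) with positive area")
  }
  if (matrix_stem_density < 0) stop("densities must be >= 0")
  patches <- lapply(patches, function(p) {
    p$polygon <- as_polygon(p$polygon)
    if (p$tall_tree_density < 0) stop("densities must be >= 0")
    if (dist_upper_support(p$tall_height_dist) > 120) {
      stop("tall height distribution support must not exceed 120 m")
    }
    bb <- apply(p$polygon, 2L, range)
    if (bb[1L, 1L] < extent[1L] || bb[2L, 1L] > extent[3L] ||
        bb[1L, 2L] < extent[2L] || bb[2L, 2L] > extent[4L]) {
      stop("patch polygons must lie inside the extent")
    }
    p
  })
  structure(list(extent = extent,
                 matrix_height_dist = matrix_height_dist,
                 matrix_stem_density = matrix_stem_density,
                 patches = patches,
                 crown_radius_coeff = crown_radius_coeff,
                 cluster_prob = cluster_prob,
                 cluster_radius = cluster_radius,
                 seed = as.integer(seed)),
            class = "forest_scenario")
}

poisson_points_in_rect <- function(density_ha, extent) {
  area_ha <- (extent[3L] - extent[1L]) * (extent[4L] - extent[2L]) / 1e4
  n <- stats::rpois(1L, density_ha * area_ha)
  cbind(x = stats::runif(n, extent[1L], extent[3L]),
        y = stats::runif(n, extent[2L], extent[4L]))
}

poisson_points_in_polygon <- function(density_ha, poly) {
  bb <- apply(poly, 2L, range)
  area_ha <- polygon_area(poly) / 1e4
  n <- stats::rpois(1L, density_ha * area_ha)
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    m <- max(16L, 2L * (n - nrow(out)))
    cand <- cbind(stats::runif(m, bb[1L, 1L], bb[2L, 1L]),
                  stats::runif(m, bb[1L, 2L], bb[2L, 2L]))
    keep <- points_in_polygon(cand[, 1L], cand[, 2L], poly)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Generate a stem map from a scenario
#'
#' Matrix stems are placed by a homogeneous Poisson process at
#' `matrix_stem_density` with heights drawn from the matrix height
#' distribution; each patch adds an independent Poisson layer of tall trees.
#' The same scenario (including its seed) always yields the identical stem
#' map.
#'
#' @param scenario a [forest_scenario()].
#' @return a `stem_map`: data.frame with columns `x`, `y`, `height_m` and
#'   attributes `extent`, `crown_radius_coeff`, `scenario_seed`.
#' @export
generate_stem_map <- function(scenario) {
  stopifnot(inherits(scenario, "forest_scenario"))
  with_seed(scenario$seed, {
    pts <- poisson_points_in_rect(scenario$matrix_stem_density, scenario$extent)
    hts <- if (nrow(pts)) sample_heights(scenario$matrix_height_dist, nrow(pts)) else numeric(0)
    for (p in scenario$patches) {
      pp <- poisson_points_in_polygon(p$tall_tree_density, p$polygon)
      ph <- if (nrow(pp)) sample_heights(p$tall_height_dist, nrow(pp)) else numeric(0)
      ph <- pmin(pmax(ph, 50), 120)  # tall layer support is [50, 120]
      pts <- rbind(pts, pp)
      hts <- c(hts, ph)
    }
    if (scenario$cluster_prob > 0 && nrow(pts)) {
      # stump-sprout leaders: offset copies within cluster_radius
      idx <- which(stats::runif(nrow(pts)) < scenario$cluster_prob)
      if (length(idx)) {
        ang <- stats::runif(length(idx), 0, 2 * pi)
        rad <- stats::runif(length(idx), 0, scenario$cluster_radius)
        ld <- cbind(pts[idx, 1L] + rad * cos(ang), pts[idx, 2L] + rad * sin(ang))
        keep <- ld[, 1L] >= scenario$extent[1L] & ld[, 1L] <= scenario$extent[3L] &
          ld[, 2L] >= scenario$extent[2L] & ld[, 2L] <= scenario$extent[4L]
        pts <- rbind(pts, ld[keep, , drop = FALSE])
        hts <- c(hts, hts[idx][keep] * stats::runif(sum(keep), 0.85, 1))
      }
    }
    sm <- data.frame(x = pts[, 1L], y = pts[, 2L], height_m = hts)
    attr(sm, "extent") <- scenario$extent
    attr(sm, "crown_radius_coeff") <- scenario$crown_radius_coeff
    attr(sm, "scenario_seed") <- scenario$seed
    class(sm) <- c("stem_map", "data.frame")
    sm
  })
}

#' @export
print.stem_map <- function(x, ...) {
  cat(sprintf("stem_map: %d stems, heights %s m\n", nrow(x),
              if (nrow(x)) sprintf("%.1f-%.1f", min(x$height_m), max(x$height_m)) else "-"))
  invisible(x)
}

#' Write / read a stem map as CSV
#'
#' Columns `x`, `y`, `height_m`; extent and crown coefficient are carried in
#' `#`-prefixed header comments so the map round-trips.
#' @param sm a stem map.
#' @param path CSV file.
#' @export
write_stem_map <- function(sm, path) {
  ext <- attr(sm, "extent")
  hdr <- c(sprintf("# extent %.10g %.10g %.10g %.10g", ext[1L], ext[2L], ext[3L], ext[4L]),
           sprintf("# crown_radius_coeff %.10g", attr(sm, "crown_radius_coeff")),
           sprintf("# scenario_seed %d", attr(sm, "scenario_seed") %||% NA_integer_))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(sm)[, c("x", "y", "height_m")], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stem_map
#' @export
read_stem_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  sm <- utils::read.csv(text = paste(body, collapse = "\n"))
  getv <- function(key) {
    l <- grep(paste0("^# ", key), hdr, value = TRUE)
    if (!length(l)) return(NULL)
    as.numeric(strsplit(trimws(sub(paste0("^# ", key), "", l[1L])), "\\s+")[[1L]])
  }
  attr(sm, "extent") <- getv("extent")
  attr(sm, "crown_radius_coeff") <- (getv("crown_radius_coeff") %||% 0.1)[1L]
  s <- getv("scenario_seed")
  attr(sm, "scenario_seed") <- if (is.null(s) || is.na(s[1L])) NA_integer_ else as.integer(s[1L])
  class(sm) <- c("stem_map", "data.frame")
  sm
}

#' Render a canopy height surface from a stem map
#'
#' Each tree contributes a paraboloid crown with apex at the tree height and
#' radius `crown_radius_coeff * height`; the surface height at distance d
#' from the stem is `h * (1 - (d / r)^2)`.  A cell takes the maximum over
#' all contributing crowns and 0 where no crown reaches, so adding a tree
#' can never lower the surface.
#'
#' @param stem_map a stem map from [generate_stem_map()] (or any data.frame
#'   with `x`, `y`, `height_m` and an `extent` attribute).
#' @param resolution cell size in metres (default 1; the spirit of a
#'   fine-resolution photogrammetric surface at desk scale).
#' @param crown_radius_coeff overrides the stem map's coefficient.
#' @param crs CRS tag.
#' @return a [grid_raster()] of canopy height above ground (m).
#' @export
render_dsm <- function(stem_map, resolution = 1,
                       crown_radius_coeff = NULL, crs = "local-metres") {
  if (resolution <= 0) stop("`resolution` must be positive")
  coeff <- crown_radius_coeff %||% attr(stem_map, "crown_radius_coeff") %||% 0.1
  ext <- attr(stem_map, "extent")
  if (is.null(ext)) {
    stop("stem map lacks an `extent` attribute")
  }
  ncol <- max(1L, ceiling((ext[3L] - ext[1L]) / resolution))
  nrow <- max(1L, ceiling((ext[4L] - ext[2L]) / resolution))
  v <- matrix(0, nrow = nrow, ncol = ncol)
  if (nrow(stem_map)) {
    xc <- ext[1L] + (seq_len(ncol) - 0.5) * resolution
    yc <- ext[2L] + (seq_len(nrow) - 0.5) * resolution
    ord <- order(stem_map$height_m)  # tallest last; pmax makes order moot
    for (k in ord) {
      tx <- stem_map$x[k]; ty <- stem_map$y[k]; h <- stem_map$height_m[k]
      r <- coeff * h
      jlo <- max(1L, ceiling((tx - r - ext[1L]) / resolution + 0.5))
      jhi <- min(ncol, floor((tx + r - ext[1L]) / resolution + 0.5))
      ilo <- max(1L, ceiling((ty - r - ext[2L]) / resolution + 0.5))
      ihi <- min(nrow, floor((ty + r - ext[2L]) / resolution + 0.5))
      if (jlo > jhi || ilo > ihi) next
      dx2 <- (xc[jlo:jhi] - tx)^2
      dy2 <- (yc[ilo:ihi] - ty)^2
      d2 <- outer(dy2, dx2, `+`)
      z <- h * (1 - d2 / (r * r))
      z[z < 0] <- 0
      v[ilo:ihi, jlo:jhi] <- pmax(v[ilo:ihi, jlo:jhi], z)
    }
  }
  grid_raster(v, xmin = ext[1L], ymin = ext[2L], res = resolution, crs = crs,
              name = "dsm")
}

#' Used (occupied) habitat polygons of a scenario
#'
#' Returns the scenario's old-growth patch polygons, which play the role of
#' occupied habitat polygons in the sampling design.
#'
#' @param scenario a [forest_scenario()].
#' @return list of polygon matrices (possibly empty).
#' @export
used_polygons_from_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "forest_scenario"))
  lapply(scenario$patches, function(p) p$polygon)
}
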
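# Planar polygon utilities.  Polygons are two-column numeric matrices of
# vertices (x, y) in projected metre coordinates, open rings (the closing
# edge from the last vertex back to the first is implicit).  Exterior rings
# are oriented counterclockwise (positive signed area).

as_polygon <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L || nrow(m) < 3L || anyNA(m)) {
    stop("a polygon must be a numeric matrix with two columns and >= 3 vertices")
  }
  storage.mode(m) <- "double"
  # strip a duplicated closing vertex if present
  if (isTRUE(all.equal(m[1L, ], m[nrow(m), ]))) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("degenerate polygon")
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' Axis-aligned rectangle polygon
#' @param xmin,ymin,xmax,ymax rectangle bounds in metres.
#' @return polygon matrix (counterclockwise).
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  if (xmax <= xmin || ymax <= ymin) stop("degenerate rectangle")
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

polygon_signed_area <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  sum(poly[j, 1L] * poly[, 2L] - poly[, 1L] * poly[j, 2L]) / 2
}

#' Area of a polygon
#'
#' Shoelace-formula area of a simple polygon given as an open vertex ring.
#'
#' @param poly two-column matrix of vertices (metres).
#' @return area in square metres.
#' @export
polygon_area <- function(poly) abs(polygon_signed_area(as_polygon(poly)))

polygon_centroid <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  cr <- poly[j, 1L] * poly[, 2L] - poly[, 1L] * poly[j, 2L]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((poly[j, 1L] + poly[, 1L]) * cr) / (6 * a),
    sum((poly[j, 2L] + poly[, 2L]) * cr) / (6 * a))
}

#' Point-in-polygon test
#'
#' Even-odd (crossing number) test, vectorised over points.
#' @param x,y point coordinates.
#' @param poly polygon matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > y) != (yj > y))
    if (any(cross)) {
      xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
      inside <- xor(inside, cross & (x < xint))
    }
    j <- i
  }
  inside
}

dist_point_segment <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / l2))
  sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
}

# Distance from points to the polygon boundary (vectorised over points).
polygon_boundary_distance <- function(x, y, poly) {
  n <- nrow(poly)
  d <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, dist_point_segment(x, y, poly[j, 1L], poly[j, 2L],
                                    poly[i, 1L], poly[i, 2L]))
    j <- i
  }
  d
}

# Distance from points to a polygon as a filled region (0 inside).
polygon_region_distance <- function(x, y, poly) {
  d <- polygon_boundary_distance(x, y, poly)
  d[points_in_polygon(x, y, poly)] <- 0
  d
}

# TRUE when the open segments (p1,p2) and (p3,p4) properly cross.
segments_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  o <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) -
    (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- o(p3, p4, p1); d2 <- o(p3, p4, p2)
  d3 <- o(p1, p2, p3); d4 <- o(p1, p2, p4)
  (d1 * d2 < -eps) && (d3 * d4 < -eps)
}

polygons_intersect <- function(a, b) {
  if (any(points_in_polygon(a[, 1L], a[, 2L], b))) return(TRUE)
  if (any(points_in_polygon(b[, 1L], b[, 2L], a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      if (segments_cross(a[i, ], a[i2, ], b[j, ], b[j2, ])) return(TRUE)
    }
  }
  FALSE
}

# Minimum distance between two polygon regions (0 when they intersect).
polygon_min_distance <- function(a, b) {
  if (polygons_intersect(a, b)) return(0)
  min(min(polygon_region_distance(a[, 1L], a[, 2L], b)),
      min(polygon_region_distance(b[, 1L], b[, 2L], a)))
}

# Drop vertices lying on the straight line between their neighbours.
simplify_collinear <- function(poly, eps = 1e-9) {
  n <- nrow(poly)
  if (n <= 3L) return(poly)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- poly[if (i == 1L) n else i - 1L, ]
    q <- poly[i, ]
    r <- poly[if (i == n) 1L else i + 1L, ]
    cr <- (q[1L] - p[1L]) * (r[2L] - p[2L]) - (q[2L] - p[2L]) * (r[1L] - p[1L])
    keep[i] <- abs(cr) > eps
  }
  if (sum(keep) < 3L) poly else poly[keep, , drop = FALSE]
}

#' Write polygons to a GeoJSON file
#'
#' Writes a list of polygons (exterior rings) as a GeoJSON FeatureCollection.
#' Coordinates are kept at full double precision so polygons round-trip
#' vertex-wise.
#'
#' @param polys a single polygon matrix or a list of them.
#' @param path output file.
#' @param properties optional data.frame of one row per polygon.
#' @param crs free-text tag recorded in the `crs_tag` top-level member
#'   (projected CRS with metre units assumed throughout the package).
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL, crs = "local-metres") {
  if (is.matrix(polys)) polys <- list(polys)
  feats <- lapply(seq_along(polys), function(i) {
    ring <- as_polygon(polys[[i]])
    ring <- rbind(ring, ring[1L, , drop = FALSE])  # GeoJSON rings are closed
    props <- if (!is.null(properties)) as.list(properties[i, , drop = FALSE]) else
      stats::setNames(list(), character(0))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1L, as.numeric,
                                                         simplify = FALSE)))))
  })
  obj <- list(type = "FeatureCollection", crs_tag = crs, features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read polygons from a GeoJSON file
#'
#' Reads the exterior ring of every Polygon feature written by
#' [write_polygons_geojson()].
#'
#' @param path GeoJSON file.
#' @return list of polygon matrices with a `properties` attribute.
#' @export
read_polygons_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  polys <- lapply(obj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(p) c(p[[1L]], p[[2L]])))
    as_polygon(ring)
  })
  props <- lapply(obj$features, function(f) f$properties)
  attr(polys, "properties") <- props
  attr(polys, "crs_tag") <- obj$crs_tag %||% "local-metres"
  polys
}
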
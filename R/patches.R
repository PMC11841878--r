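# Habitat patch delineation: polygonize low-or-better cells, buffer by the
# 5-acre window radius, group tall TAOs by dissolved buffer region, wrap
# each group in a concave hull, and smooth the perimeter with a 60-m
# outward / 55-m inward morphological buffer pair.

# ---- raster polygonization -------------------------------------------------

# Connected components (4-connectivity) of TRUE cells.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        ii <- nb[1L]; jj <- nb[2L]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- c(queue, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  lab
}

# Trace the boundary rings of a cell set.  Directed edges keep the interior
# on the left, so exterior rings come out counterclockwise; at pinch
# corners the sharpest-left turn is taken, which keeps rings simple.
trace_rings <- function(cells, nr, nc, xmin, ymin, res) {
  inset <- matrix(FALSE, nr + 2L, nc + 2L)
  ci <- (cells - 1L) %% nr + 1L
  cj <- (cells - 1L) %/% nr + 1L
  inset[cbind(ci + 1L, cj + 1L)] <- TRUE  # pad so edge tests never index out
  idx <- which(inset, arr.ind = TRUE)
  edges <- list()
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]  # padded indices
    x0 <- (j - 2L) * res; x1 <- (j - 1L) * res
    y0 <- (i - 2L) * res; y1 <- (i - 1L) * res
    if (!inset[i - 1L, j]) edges[[length(edges) + 1L]] <- c(x0, y0, x1, y0)
    if (!inset[i, j + 1L]) edges[[length(edges) + 1L]] <- c(x1, y0, x1, y1)
    if (!inset[i + 1L, j]) edges[[length(edges) + 1L]] <- c(x1, y1, x0, y1)
    if (!inset[i, j - 1L]) edges[[length(edges) + 1L]] <- c(x0, y1, x0, y0)
  }
  if (!length(edges)) return(list())
  E <- do.call(rbind, edges)
  key <- function(x, y) paste(round(x / res), round(y / res))
  starts <- key(E[, 1L], E[, 2L])
  bystart <- split(seq_len(nrow(E)), starts)
  used <- logical(nrow(E))
  rings <- list()
  for (e0 in seq_len(nrow(E))) {
    if (used[e0]) next
    ring <- list(E[e0, 1:2])
    cur <- e0
    used[e0] <- TRUE
    repeat {
      endk <- key(E[cur, 3L], E[cur, 4L])
      cand <- bystart[[endk]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # sharpest left turn relative to the incoming direction
        din <- c(E[cur, 3L] - E[cur, 1L], E[cur, 4L] - E[cur, 2L])
        ang <- vapply(cand, function(e) {
          dout <- c(E[e, 3L] - E[e, 1L], E[e, 4L] - E[e, 2L])
          atan2(din[1L] * dout[2L] - din[2L] * dout[1L],
                din[1L] * dout[1L] + din[2L] * dout[2L])
        }, 0)
        cand <- cand[which.max(ang)]
      }
      nxt <- cand[1L]
      ring[[length(ring) + 1L]] <- E[nxt, 1:2]
      used[nxt] <- TRUE
      cur <- nxt
      if (key(E[cur, 3L], E[cur, 4L]) == key(ring[[1L]][1L], ring[[1L]][2L])) break
    }
    m <- do.call(rbind, ring)
    m[, 1L] <- m[, 1L] + xmin
    m[, 2L] <- m[, 2L] + ymin
    if (nrow(m) >= 3L) rings[[length(rings) + 1L]] <- m
  }
  rings
}

#' Polygonize qualifying habitat cells
#'
#' Dissolves cells whose class code is at least `min_class` into polygons,
#' one per 4-connected component (diagonal-only neighbours stay separate).
#' Exterior rings only (counterclockwise); interior holes are dropped, as
#' patch grouping needs only the outer boundary.
#'
#' @param class_raster integer-coded class raster from [classify_grid()].
#' @param min_class minimum qualifying class: a label (e.g. `"low"`) when
#'   the raster carries its classes, or an integer code.
#' @return list of polygons (possibly empty).
#' @export
habitat_mask <- function(class_raster, min_class = "low") {
  cls <- attr(class_raster, "classes")
  code <- if (is.character(min_class)) {
    if (is.null(cls)) stop("raster carries no class labels; give a numeric code")
    m <- match(min_class, cls$labels)
    if (is.na(m)) stop("unknown class label")
    m - 1L
  } else as.integer(min_class)
  mask <- class_raster$values >= code
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  polys <- list()
  for (g in seq_len(max(lab))) {
    rings <- trace_rings(which(lab == g), nrow(mask), ncol(mask),
                         class_raster$xmin, class_raster$ymin,
                         class_raster$res)
    if (!length(rings)) next
    areas <- vapply(rings, polygon_signed_area, 0)
    ext <- rings[[which.max(areas)]]  # exterior ring: largest positive area
    polys[[length(polys) + 1L]] <- simplify_collinear(as_polygon(ext))
  }
  polys
}

# ---- buffering and grouping -----------------------------------------------

#' Group tall TAOs by dissolved habitat buffers
#'
#' Each mask polygon is (conceptually) buffered outward by `buffer` metres;
#' buffers that overlap dissolve into one region, and every TAO at least
#' `tao_min_height` tall lying inside a dissolved region joins that
#' region's group.  Implemented with exact polygon distances: buffers of
#' two polygons overlap iff the polygons are within `2 * buffer` of each
#' other, and a TAO lies in a buffer iff it is within `buffer` of the
#' polygon.
#'
#' @param mask_polygons list of polygons from [habitat_mask()].
#' @param taos a `tao_set`.
#' @param buffer outward buffer distance in metres (default 80.25, the
#'   5-acre window radius).
#' @param tao_min_height minimum TAO height (default 50 m).
#' @return list of groups, each `list(polygons =, taos =)` (taos a
#'   data.frame subset); TAO-less groups are kept with 0 rows.
#' @export
buffer_and_collect <- function(mask_polygons, taos, buffer = 80.25,
                               tao_min_height = 50) {
  if (buffer < 0) stop("`buffer` must be >= 0")
  np <- length(mask_polygons)
  if (!np) return(list())
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (np > 1L) {
    for (a in seq_len(np - 1L)) for (b in (a + 1L):np) {
      if (polygon_min_distance(mask_polygons[[a]], mask_polygons[[b]]) <= 2 * buffer) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(np), find, 0L)
  tall <- taos[taos$height_m >= tao_min_height, , drop = FALSE]
  dmat <- matrix(Inf, nrow(tall), np)
  for (p in seq_len(np)) {
    if (nrow(tall)) {
      dmat[, p] <- polygon_region_distance(tall$x, tall$y, mask_polygons[[p]])
    }
  }
  groups <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    inbuf <- if (nrow(tall)) {
      apply(dmat[, members, drop = FALSE], 1L, min) <= buffer
    } else logical(0)
    groups[[length(groups) + 1L]] <-
      list(polygons = mask_polygons[members],
           taos = tall[inbuf, , drop = FALSE])
  }
  groups
}

# ---- concave hull ----------------------------------------------------------

#' Concave hull of a point set
#'
#' The edge-digging concave hull: starting from the convex hull, any hull
#' edge longer than `length_threshold` may be replaced by two edges through
#' the interior point nearest to it, provided the point is within
#' `edge_length / concavity` of both endpoints' reach and the new edges do
#' not cross the hull.  Smaller `concavity` digs deeper; as
#' `concavity -> Inf` the result converges to the convex hull.  All input
#' points remain inside or on the hull.
#'
#' @param points two-column matrix of point coordinates (>= 3 points, not
#'   all collinear).
#' @param concavity relative concavity parameter (default 0.8).
#' @param length_threshold edges shorter than this are never dug (default
#'   0).
#' @return polygon matrix (counterclockwise), or `NULL` (with a warning)
#'   for degenerate input.
#' @export
concave_hull <- function(points, concavity = 0.8, length_threshold = 0) {
  pts <- unique(as.matrix(points))
  if (nrow(pts) < 3L) {
    warning("fewer than 3 distinct points; no hull")
    return(NULL)
  }
  ch <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(ch) < 3L) {
    warning("collinear points; no hull")
    return(NULL)
  }
  hull <- rev(ch)  # chull is clockwise; reverse to counterclockwise
  interior <- setdiff(seq_len(nrow(pts)), hull)
  # hull as a vertex index ring; process edges queue-wise
  ring <- hull
  queue <- seq_along(ring)  # edge i: ring[i] -> ring[i+1 (wrap)]
  sq_thresh <- length_threshold^2
  sqc <- concavity^2
  edge_pts <- function(i) {
    a <- pts[ring[i], ]; b <- pts[ring[if (i == length(ring)) 1L else i + 1L], ]
    list(a = a, b = b)
  }
  crosses_hull <- function(p, a, b) {
    n <- length(ring)
    for (i in seq_len(n)) {
      u <- pts[ring[i], ]; v <- pts[ring[if (i == n) 1L else i + 1L], ]
      if (segments_cross(a, p, u, v) || segments_cross(p, b, u, v)) return(TRUE)
    }
    FALSE
  }
  guard <- 0L
  while (length(interior) && guard < 10000L) {
    guard <- guard + 1L
    dug <- FALSE
    n <- length(ring)
    i <- 1L
    while (i <= n) {
      e <- edge_pts(i)
      sq_len <- sum((e$b - e$a)^2)
      if (sq_len >= sq_thresh && sq_len > 0) {
        max_sq <- sq_len / sqc
        d <- dist_point_segment(pts[interior, 1L], pts[interior, 2L],
                                e$a[1L], e$a[2L], e$b[1L], e$b[2L])
        ord <- order(d)
        for (cnd in ord) {
          p_idx <- interior[cnd]
          p <- pts[p_idx, ]
          reach <- min(sum((p - e$a)^2), sum((p - e$b)^2))
          if (reach > max_sq) break  # ordered by distance; none closer fits
          if (!crosses_hull(p, e$a, e$b)) {
            ring <- append(ring, p_idx, after = i)
            interior <- setdiff(interior, p_idx)
            dug <- TRUE
            break
          }
        }
        if (dug) break  # restart scan with the updated ring
      }
      i <- i + 1L
    }
    if (!dug) break
  }
  as_polygon(pts[ring, , drop = FALSE])
}

# ---- perimeter smoothing ---------------------------------------------------

#' Morphological perimeter smoothing
#'
#' Buffers the polygon outward by `out` metres and back inward by `in_` --
#' a morphological closing by `in_` composed with a dilation by
#' `out - in_`.  Bays narrower than about `2 * in_` are filled, and the
#' result always contains the input (dilated by the `out - in_` margin).
#' The outward distance field is computed exactly from the polygon edges;
#' the inward step uses a Euclidean distance transform on a working grid
#' of `resolution` metres, and the result is polygonized from that grid.
#'
#' @param polygon input polygon.
#' @param out outward buffer distance (default 60).
#' @param in_ inward buffer distance (default 55; must not exceed `out`).
#' @param resolution working-grid cell size in metres (default 1).
#' @return smoothed polygon (largest exterior ring).
#' @export
smooth_perimeter <- function(polygon, out = 60, in_ = 55, resolution = 1) {
  if (is.null(polygon)) return(NULL)
  polygon <- as_polygon(polygon)
  if (in_ > out) stop("`in_` must not exceed `out`")
  bb <- apply(polygon, 2L, range)
  pad <- out + 2 * resolution
  x0 <- bb[1L, 1L] - pad; y0 <- bb[1L, 2L] - pad
  nc <- ceiling((bb[2L, 1L] + pad - x0) / resolution)
  nr <- ceiling((bb[2L, 2L] + pad - y0) / resolution)
  xc <- x0 + (seq_len(nc) - 0.5) * resolution
  yc <- y0 + (seq_len(nr) - 0.5) * resolution
  gx <- rep(xc, each = nr)
  gy <- rep(yc, times = nc)
  d <- matrix(polygon_region_distance(gx, gy, polygon), nr, nc)
  dil <- d <= out
  if (in_ > 0) {
    dm <- EBImage::distmap(EBImage::Image(dil * 1), metric = "euclidean")
    ero <- EBImage::imageData(dm) * resolution > in_
  } else {
    ero <- dil
  }
  cells <- which(ero)
  if (!length(cells)) return(NULL)
  lab <- label_components(ero)
  # keep the component containing the input polygon (largest by cell count)
  counts <- tabulate(lab[lab > 0L])
  main <- which.max(counts)
  rings <- trace_rings(which(lab == main), nr, nc, x0, y0, resolution)
  areas <- vapply(rings, polygon_signed_area, 0)
  simplify_collinear(as_polygon(rings[[which.max(areas)]]))
}

# ---- patch assembly --------------------------------------------------------

#' Delineate habitat patches
#'
#' End-to-end patch construction: polygonize low-or-better cells, group
#' tall TAOs by the dissolved `buffer`-metre regions, hull each group with
#' at least three non-collinear TAOs (smaller groups are dropped with a
#' warning -- one or two trees do not delineate a stand), and smooth each
#' hull's perimeter.
#'
#' @param class_raster integer class raster from [classify_grid()].
#' @param taos a `tao_set`.
#' @param min_class minimum qualifying class (default `"low"`).
#' @param buffer outward buffer (default 80.25 m).
#' @param tao_min_height TAO height filter (default 50 m).
#' @param concavity,length_threshold concave-hull parameters (defaults 0.8
#'   and 0).
#' @param smooth_out,smooth_in perimeter smoothing distances (defaults 60
#'   and 55 m).
#' @param resolution smoothing working-grid resolution (m).
#' @return list of `list(polygon =, hull =, taos =)` per retained patch.
#' @export
delineate_patches <- function(class_raster, taos, min_class = "low",
                              buffer = 80.25, tao_min_height = 50,
                              concavity = 0.8, length_threshold = 0,
                              smooth_out = 60, smooth_in = 55,
                              resolution = 1) {
  mask <- habitat_mask(class_raster, min_class)
  groups <- buffer_and_collect(mask, taos, buffer, tao_min_height)
  out <- list()
  for (g in groups) {
    if (nrow(g$taos) < 3L) {
      warning(sprintf("dropping a buffer group with %d tall TAO(s); too few to hull",
                      nrow(g$taos)))
      next
    }
    hull <- concave_hull(cbind(g$taos$x, g$taos$y), concavity, length_threshold)
    if (is.null(hull)) {
      warning("dropping a degenerate (collinear) buffer group")
      next
    }
    poly <- smooth_perimeter(hull, smooth_out, smooth_in, resolution)
    out[[length(out) + 1L]] <- list(polygon = poly, hull = hull, taos = g$taos)
  }
  out
}

#' Summarise patches into a patch set
#'
#' Per patch: polygon area (hectares and acres), mean/median/max HSI over
#' the covered cells, hectares per habitat class, and used/available
#' status by intersection with the used polygons.  Patches are ordered by
#' descending area, ties by centroid (x then y).
#'
#' @param patches list from [delineate_patches()].
#' @param hsi_raster HSI [grid_raster()].
#' @param class_raster classified [grid_raster()].
#' @param used_polygons list of used polygons (may be empty).
#' @return a `patch_set` data.frame with one row per patch and the patch
#'   polygons in `attr(, "polygons")`.
#' @export
summarize_patches <- function(patches, hsi_raster, class_raster,
                              used_polygons = list()) {
  if (!length(patches)) {
    out <- data.frame(patch = integer(0), area_ha = numeric(0),
                      area_ac = numeric(0), n_taos = integer(0),
                      mean_hsi = numeric(0), median_hsi = numeric(0),
                      max_hsi = numeric(0), status = character(0))
    attr(out, "polygons") <- list()
    class(out) <- c("patch_set", "data.frame")
    return(out)
  }
  cls <- attr(class_raster, "classes")
  labels <- if (!is.null(cls)) cls$labels else
    paste0("class_", sort(unique(as.integer(class_raster$values))))
  ext <- raster_extent(hsi_raster)
  rows <- list(); polys <- list()
  for (pi in seq_along(patches)) {
    poly <- patches[[pi]]$polygon
    bb <- apply(poly, 2L, range)
    if (bb[1L, 1L] < ext["xmin"] - hsi_raster$res || bb[2L, 1L] > ext["xmax"] + hsi_raster$res ||
        bb[1L, 2L] < ext["ymin"] - hsi_raster$res || bb[2L, 2L] > ext["ymax"] + hsi_raster$res) {
      # tolerate smoothing margins that overhang slightly; reject gross misfits
      if (bb[1L, 1L] > ext["xmax"] || bb[2L, 1L] < ext["xmin"] ||
          bb[1L, 2L] > ext["ymax"] || bb[2L, 2L] < ext["ymin"]) {
        stop("patch polygon lies outside the raster")
      }
    }
    xs <- cell_centers_x(hsi_raster); ys <- cell_centers_y(hsi_raster)
    js <- which(xs >= bb[1L, 1L] & xs <= bb[2L, 1L])
    is <- which(ys >= bb[1L, 2L] & ys <= bb[2L, 2L])
    gx <- rep(xs[js], each = length(is)); gy <- rep(ys[is], times = length(js))
    inside <- points_in_polygon(gx, gy, poly)
    hsis <- hsi_raster$values[as.matrix(expand.grid(is, js))][inside]
    codes <- class_raster$values[as.matrix(expand.grid(is, js))][inside]
    cell_ha <- hsi_raster$res^2 / 1e4
    class_ha <- vapply(seq_along(labels) - 1L,
                       function(cd) sum(codes == cd) * cell_ha, 0)
    names(class_ha) <- paste0("class_ha_", labels)
    status <- "available"
    for (up in used_polygons) {
      if (polygons_intersect(poly, as_polygon(up))) { status <- "used"; break }
    }
    rows[[pi]] <- c(list(area_ha = polygon_area(poly) / 1e4,
                         area_ac = polygon_area(poly) / ACRE_M2,
                         n_taos = nrow(patches[[pi]]$taos),
                         mean_hsi = if (length(hsis)) mean(hsis) else NA_real_,
                         median_hsi = if (length(hsis)) stats::median(hsis) else NA_real_,
                         max_hsi = if (length(hsis)) max(hsis) else NA_real_,
                         status = status),
                    as.list(class_ha))
    polys[[pi]] <- poly
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  cen <- t(vapply(polys, polygon_centroid, numeric(2L)))
  ord <- order(-out$area_ha, cen[, 1L], cen[, 2L])
  out <- out[ord, , drop = FALSE]
  out <- cbind(patch = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "polygons") <- polys[ord]
  class(out) <- c("patch_set", "data.frame")
  out
}

#' Write a patch set as GeoJSON
#' @param patch_set from [summarize_patches()].
#' @param path GeoJSON path.
#' @export
write_patches <- function(patch_set, path) {
  write_polygons_geojson(attr(patch_set, "polygons"), path,
                         properties = as.data.frame(patch_set))
  invisible(path)
}
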
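# Tree-approximate-object (TAO) extraction: local maxima of the canopy
# surface within a circular window.

#' Extract tree approximate objects from a canopy surface
#'
#' A cell is a TAO when its value is positive, at least `min_height`, and
#' greater than or equal to every cell whose centre lies within
#' `window_radius` of its own centre (circular neighbourhood, clipped at the
#' raster edge).  Plateaus -- connected runs of equal-valued jointly maximal
#' cells -- emit a single TAO at the plateau cell closest to the plateau
#' centroid, ties broken by row-major scan order, so detection is fully
#' deterministic.
#'
#' @param dsm a [grid_raster()] canopy height surface (m above ground).
#' @param window_radius circular window radius in metres (default 2; must
#'   be at least the raster resolution).
#' @param min_height minimum height for a cell to be considered (m).
#' @return a `tao_set`: data.frame with columns `x`, `y`, `height_m` plus
#'   detection parameters as attributes.
#' @export
extract_taos <- function(dsm, window_radius = 2, min_height = 0) {
  stopifnot(inherits(dsm, "grid_raster"))
  if (window_radius < dsm$res) {
    stop("`window_radius` must be at least the raster resolution")
  }
  if (min_height < 0) stop("`min_height` must be >= 0")
  v <- dsm$values
  nr <- nrow(v); nc <- ncol(v)
  w <- ceiling(window_radius / dsm$res)
  offs <- expand.grid(di = -w:w, dj = -w:w)
  keep <- (offs$di^2 + offs$dj^2) * dsm$res^2 <= window_radius^2 &
    !(offs$di == 0 & offs$dj == 0)
  offs <- offs[keep, , drop = FALSE]

  cand <- v > 0 & v >= min_height
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    sh <- matrix(-Inf, nr, nc)
    ri <- max(1L, 1L - di):min(nr, nr - di)   # rows of v receiving a neighbour
    ci <- max(1L, 1L - dj):min(nc, nc - dj)
    sh[ri, ci] <- v[ri + di, ci + dj]
    cand <- cand & (v >= sh)
    if (!any(cand)) break
  }

  idx <- which(cand, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(empty_tao_set(dsm, window_radius, min_height))
  }

  # collapse plateaus: 8-connected equal-valued candidate cells -> one TAO
  ord <- order(idx[, 1L], idx[, 2L])  # row-major scan order
  idx <- idx[ord, , drop = FALSE]
  key <- (idx[, 1L] - 1L) * nc + idx[, 2L]
  lookup <- new.env(hash = TRUE, size = nrow(idx))
  for (i in seq_len(nrow(idx))) assign(as.character(key[i]), i, envir = lookup)
  comp <- integer(nrow(idx))
  ncomp <- 0L
  for (i in seq_len(nrow(idx))) {
    if (comp[i] != 0L) next
    ncomp <- ncomp + 1L
    queue <- i
    comp[i] <- ncomp
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      ci <- idx[cur, 1L]; cj <- idx[cur, 2L]
      val <- v[ci, cj]
      for (di in -1L:1L) for (dj in -1L:1L) {
        if (di == 0L && dj == 0L) next
        nk <- as.character((ci + di - 1L) * nc + (cj + dj))
        j <- mget(nk, envir = lookup, ifnotfound = list(NULL))[[1L]]
        if (!is.null(j) && comp[j] == 0L && v[idx[j, 1L], idx[j, 2L]] == val) {
          comp[j] <- ncomp
          queue <- c(queue, j)
        }
      }
    }
  }
  rows <- integer(ncomp)
  for (g in seq_len(ncomp)) {
    members <- which(comp == g)
    if (length(members) == 1L) {
      rows[g] <- members
    } else {
      cen <- colMeans(idx[members, , drop = FALSE])
      d2 <- (idx[members, 1L] - cen[1L])^2 + (idx[members, 2L] - cen[2L])^2
      rows[g] <- members[which.min(d2)]  # members already in row-major order
    }
  }
  rows <- sort(rows)
  taos <- data.frame(
    x = dsm$xmin + (idx[rows, 2L] - 0.5) * dsm$res,
    y = dsm$ymin + (idx[rows, 1L] - 0.5) * dsm$res,
    height_m = v[idx[rows, , drop = FALSE]])
  tao_set(taos, dsm, window_radius, min_height)
}

tao_set <- function(df, dsm = NULL, window_radius = NA, min_height = NA) {
  attr(df, "source") <- list(raster = if (!is.null(dsm)) dsm$name else NA,
                             window_radius = window_radius,
                             min_height = min_height,
                             crs = if (!is.null(dsm)) dsm$crs else "local-metres")
  class(df) <- c("tao_set", "data.frame")
  df
}

empty_tao_set <- function(dsm = NULL, window_radius = NA, min_height = NA) {
  tao_set(data.frame(x = numeric(0), y = numeric(0), height_m = numeric(0)),
          dsm, window_radius, min_height)
}

#' @export
print.tao_set <- function(x, ...) {
  cat(sprintf("tao_set: %d TAOs", nrow(x)))
  if (nrow(x)) cat(sprintf(", heights %.1f-%.1f m", min(x$height_m), max(x$height_m)))
  cat("\n")
  invisible(x)
}

#' Filter TAOs by minimum height
#'
#' Keeps TAOs with `height_m >= min_height` (boundary inclusive), preserving
#' order.
#'
#' @param taos a `tao_set`.
#' @param min_height threshold in metres.
#' @export
filter_taos <- function(taos, min_height) {
  out <- taos[taos$height_m >= min_height, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$source <- attr(taos, "source")
  class(out) <- class(taos)
  out
}

#' Write / read TAO sets as CSV
#' @param taos a `tao_set`.
#' @param path CSV file with columns `x`, `y`, `height_m`.
#' @export
write_taos <- function(taos, path) {
  utils::write.csv(as.data.frame(taos)[, c("x", "y", "height_m")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_taos
#' @export
read_taos <- function(path) {
  tao_set(utils::read.csv(path))
}
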
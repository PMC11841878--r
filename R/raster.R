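# A minimal single-band raster on a regular grid in projected metre
# coordinates.  `values` is a matrix with rows running south -> north
# (row 1 is the southernmost row) and columns west -> east, so that
# cell (i, j) has centre (xmin + (j - 0.5) res, ymin + (i - 0.5) res).

#' Construct a grid raster
#'
#' @param values numeric matrix, rows south to north.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (m).
#' @param res cell size (m), square cells.
#' @param crs free-text CRS tag (projected, metre units).
#' @param name optional layer name.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, res = 1,
                        crs = "local-metres", name = "layer") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (res <= 0) stop("`res` must be positive")
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res,
                 crs = crs, name = name),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster '%s': %d rows x %d cols @ %g m, origin (%g, %g), crs %s\n",
              x$name, nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin, x$crs))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g]\n", rng[1L], rng[2L]))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xmin, ymin = r$ymin,
    xmax = r$xmin + ncol(r$values) * r$res,
    ymax = r$ymin + nrow(r$values) * r$res)
}

cell_centers_x <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$res
cell_centers_y <- function(r) r$ymin + (seq_len(nrow(r$values)) - 0.5) * r$res

# Half-open cell lookup: a point on a cell boundary belongs to the cell to
# its east/north, i.e. column j covers [xmin + (j-1) res, xmin + j res).
cell_index <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$res) + 1L
  row <- floor((y - r$ymin) / r$res) + 1L
  ok <- col >= 1L & col <= ncol(r$values) & row >= 1L & row <= nrow(r$values)
  cbind(row = as.integer(row), col = as.integer(col), inside = ok)
}

raster_lookup <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- idx[, "inside"] == 1
  out[ok] <- r$values[cbind(idx[ok, "row"], idx[ok, "col"])]
  out
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$res - b$res) < tol &&
    nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (`.asc`); readable by standard GIS
#' software.  Rows are written north to south as the format requires.
#'
#' @param r a [grid_raster()].
#' @param path output file.
#' @param nodata value used for `NA` cells (default -9999).
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", r$xmin),
               sprintf("yllcorner %.10g", r$ymin),
               sprintf("cellsize %.10g", r$res),
               sprintf("NODATA_value %g", nodata)), con)
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(format(v[i, ], trim = TRUE, digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_asc()] or other software.
#' @param crs CRS tag to attach.
#' @param name layer name to attach.
#' @return a [grid_raster()].
#' @export
read_asc <- function(path, crs = "local-metres", name = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  v <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # back to south-first rows
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  grid_raster(v, xmin = xll, ymin = yll, res = hdr$cellsize, crs = crs,
              name = name %||% sub("\\.asc$", "", basename(path)))
}
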
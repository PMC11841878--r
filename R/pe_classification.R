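# Continuous predicted-to-expected (P/E, continuous Boyce) ratio curve,
# smoothing, the forced unsuitable break, exhaustive piecewise-linear
# breakpoint search, and classification of HSI grids.

#' Continuous P/E ratio curve
#'
#' Overlapping HSI bins of width `width` centred from `start` to the
#' maximum prediction in steps of `step`.  Per bin, P is the fraction of
#' used predictions falling in the bin, E the fraction of available
#' predictions, and P/E their ratio; bins with no available mass are
#' flagged undefined and excluded from smoothing and fitting.
#'
#' @param used_hsi,available_hsi HSI predictions of the used and available
#'   samples (both nonempty).
#' @param width bin width (default 0.02).
#' @param step centre spacing (default 0.002).
#' @param start first bin centre (default 0.02).
#' @return a `pe_curve` data.frame: `center`, `n_used`, `n_available`,
#'   `p`, `e`, `pe`, `defined`, and `smoothed` (NA until [smooth_pe()]).
#' @export
pe_curve <- function(used_hsi, available_hsi, width = 0.02, step = 0.002,
                     start = 0.02) {
  if (!length(used_hsi) || !length(available_hsi)) stop("both samples must be nonempty")
  if (width <= step) stop("`width` must exceed `step`")
  if (stats::sd(available_hsi) == 0) stop("constant predictions give a degenerate curve")
  top <- max(used_hsi, available_hsi)
  centers <- seq(start, max(start, top), by = step)
  su <- sort(used_hsi); sa <- sort(available_hsi)
  half <- width / 2
  cu <- findInterval(centers + half, su) - findInterval(centers - half, su,
                                                        left.open = TRUE)
  ca <- findInterval(centers + half, sa) - findInterval(centers - half, sa,
                                                        left.open = TRUE)
  p <- cu / length(used_hsi)
  e <- ca / length(available_hsi)
  out <- data.frame(center = centers, n_used = cu, n_available = ca,
                    p = p, e = e,
                    pe = ifelse(ca > 0, p / e, NA_real_),
                    defined = ca > 0,
                    smoothed = NA_real_)
  attr(out, "width") <- width
  attr(out, "step") <- step
  class(out) <- c("pe_curve", "data.frame")
  out
}

#' Smooth a P/E curve
#'
#' Fixed-span local-linear running smoother over the defined bins: each
#' smoothed value is the prediction at its own centre of an ordinary
#' least-squares line fitted to the nearest `span` fraction of defined
#' bins.  Reproduces straight-line curves exactly and never changes the
#' number of bins; raw values are retained alongside.
#'
#' @param curve a [pe_curve()] with at least 10 defined bins.
#' @param span fraction of defined bins per local fit (default 0.2).
#' @return the curve with its `smoothed` column filled (defined bins only).
#' @export
smooth_pe <- function(curve, span = 0.2) {
  def <- which(curve$defined)
  if (length(def) < 10L) stop("need at least 10 defined bins to smooth")
  x <- curve$center[def]; y <- curve$pe[def]
  m <- length(def)
  k <- max(3L, ceiling(span * m))
  sm <- numeric(m)
  for (i in seq_len(m)) {
    lo <- max(1L, i - k %/% 2L)
    hi <- min(m, lo + k - 1L)
    lo <- max(1L, hi - k + 1L)
    xx <- x[lo:hi]; yy <- y[lo:hi]
    if (stats::sd(xx) == 0) {
      sm[i] <- mean(yy)
    } else {
      b <- stats::cov(xx, yy) / stats::var(xx)
      sm[i] <- mean(yy) + b * (x[i] - mean(xx))
    }
  }
  curve$smoothed <- NA_real_
  curve$smoothed[def] <- sm
  curve
}

pe_values <- function(curve) {
  ifelse(is.na(curve$smoothed), curve$pe, curve$smoothed)
}

#' Forced unsuitable break
#'
#' The first habitat breakpoint is forced at the maximum bin centre whose
#' (smoothed, falling back to raw) P/E ratio is below 1: habitat used less
#' than its availability predicts is unsuitable by construction.
#'
#' @param curve a [pe_curve()], ideally smoothed.
#' @return HSI value of the forced break.
#' @export
forced_unsuitable_break <- function(curve) {
  def <- which(curve$defined)
  vals <- pe_values(curve)[def]
  below <- def[vals < 1]
  if (!length(below)) {
    warning("no bin with P/E < 1; forcing the break at the first bin centre")
    return(curve$center[def[1L]])
  }
  if (length(below) == length(def)) {
    warning("P/E < 1 everywhere; the curve shows no selection")
  }
  max(curve$center[below])
}

piecewise_design <- function(x, breaks) {
  cbind(1, x, vapply(breaks, function(b) pmax(0, x - b), numeric(length(x))))
}

fit_piecewise_ols <- function(x, y, breaks) {
  X <- piecewise_design(x, breaks)
  f <- stats::.lm.fit(X, y)
  sse <- sum(f$residuals^2)
  list(coef = f$coefficients, sse = sse)
}

#' Exhaustive piecewise-linear breakpoint search
#'
#' Fits a continuous piecewise-linear function to the (smoothed) P/E
#' values over bin centres at or above the forced break, by ordinary
#' least-squares for every combination of `k` interior breakpoints chosen
#' from the candidate bin centres, and returns the combination with the
#' smallest SSE (ties resolved to the lexicographically smallest set).
#' When the number of candidates would make the exact search explode, the
#' candidate set is thinned to at most `max_candidates` evenly spaced
#' centres before the (still exhaustive) search.
#'
#' @param curve a [pe_curve()] (smoothed values are used where present).
#' @param k number of interior breakpoints (>= 0; default 5).
#' @param forced_break the forced first break from
#'   [forced_unsuitable_break()].
#' @param max_candidates candidate-grid cap (default 22).
#' @return a `breakpoint_fit`: `breaks` (sorted interior breakpoints),
#'   `forced_break`, `coef`, `sse`, `candidates`, plus segment
#'   slopes/intercepts.
#' @export
fit_breakpoints <- function(curve, k = 5, forced_break, max_candidates = 22) {
  def <- which(curve$defined & curve$center >= forced_break)
  x <- curve$center[def]
  y <- pe_values(curve)[def]
  cand <- x[x > forced_break & x < max(x)]
  if (k < 0) stop("`k` must be >= 0")
  if (k > 0 && length(cand) < k) stop("more breakpoints than candidate centres")
  if (k > 0 && length(cand) > max_candidates) {
    cand <- cand[unique(round(seq(1, length(cand), length.out = max_candidates)))]
  }
  if (k == 0) {
    best <- fit_piecewise_ols(x, y, numeric(0))
    best_breaks <- numeric(0)
  } else {
    combos <- utils::combn(length(cand), k)
    best <- NULL; best_breaks <- NULL
    for (ci in seq_len(ncol(combos))) {
      br <- cand[combos[, ci]]
      f <- fit_piecewise_ols(x, y, br)
      if (is.null(best) || f$sse < best$sse - 1e-12) {
        best <- f; best_breaks <- br
      }
    }
  }
  # per-segment slope/intercept from the hinge coefficients
  slopes <- cumsum(c(best$coef[2L], best$coef[-(1:2)]))
  structure(list(forced_break = forced_break, breaks = best_breaks,
                 coef = best$coef, sse = best$sse,
                 segment_slopes = slopes,
                 candidates = cand, n_points = length(x)),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("breakpoint_fit: forced %.3f + interior {%s}, SSE %.4g over %d bins\n",
              x$forced_break, paste(sprintf("%.3f", x$breaks), collapse = ", "),
              x$sse, x$n_points))
  invisible(x)
}

#' Assemble habitat classes from breakpoints
#'
#' Boundaries are the forced break, the retained interior breakpoints
#' (after any explicit merges -- removing a breakpoint merges its adjacent
#' classes, mirroring the judgment step of collapsing anomalous or
#' immaterial segments), and the maximum HSI.  With four boundaries the
#' classic labels unsuitable/marginal/low/medium/high apply.
#'
#' @param forced_break forced first break.
#' @param fit a `breakpoint_fit` (or numeric vector of interior breaks).
#' @param max_hsi top of the classified range.
#' @param merges breakpoints to remove (must exist in the fit).
#' @param labels class labels, length = number of boundaries + 1; default
#'   the five standard labels when that length fits, else `class_0..n`.
#' @return a `habitat_classes`: `boundaries` (increasing, starting at 0
#'   implicitly) and `labels`.
#' @export
build_classes <- function(forced_break, fit, max_hsi, merges = numeric(0),
                          labels = NULL) {
  breaks <- if (inherits(fit, "breakpoint_fit")) fit$breaks else as.numeric(fit)
  if (length(merges)) {
    miss <- merges[!vapply(merges, function(m) any(abs(breaks - m) < 1e-9), TRUE)]
    if (length(miss)) stop("merges reference breakpoints not in the fit")
    keep <- !vapply(breaks, function(b) any(abs(merges - b) < 1e-9), TRUE)
    breaks <- breaks[keep]
  }
  bounds <- sort(unique(c(forced_break, breaks, max_hsi)))
  n_class <- length(bounds)  # [0,forced), segments, top class closed
  if (is.null(labels)) {
    labels <- if (n_class == 5L) {
      c("unsuitable", "marginal", "low", "medium", "high")
    } else paste0("class_", seq_len(n_class) - 1L)
  }
  if (length(labels) != n_class) stop("label count mismatch")
  structure(list(boundaries = bounds, labels = labels), class = "habitat_classes")
}

#' @export
print.habitat_classes <- function(x, ...) {
  lo <- c(0, x$boundaries[-length(x$boundaries)])
  hi <- x$boundaries
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-10s %.3f - %.3f\n", x$labels[i], lo[i], hi[i]))
  }
  invisible(x)
}

#' Class code of HSI values
#'
#' Left-closed, right-open intervals `[b_i, b_{i+1})`; the top class is
#' closed above.  Codes run 0 (lowest class) upward.
#'
#' @param hsi numeric HSI values (must be >= 0).
#' @param classes a `habitat_classes`.
#' @export
classify_hsi <- function(hsi, classes) {
  if (any(hsi < 0, na.rm = TRUE)) stop("negative HSI values")
  top <- classes$boundaries[length(classes$boundaries)]
  if (any(hsi > top + 1e-9, na.rm = TRUE)) {
    warning("HSI values above the top boundary clamped to the top class")
  }
  code <- findInterval(hsi, classes$boundaries, left.open = FALSE)
  pmin(code, length(classes$labels) - 1L)
}

#' Classify an HSI raster
#'
#' @param hsi_raster a [grid_raster()] of HSI values.
#' @param classes a `habitat_classes`.
#' @return an integer-coded [grid_raster()] (0 = lowest class) carrying
#'   the classes as an attribute.
#' @export
classify_grid <- function(hsi_raster, classes) {
  v <- hsi_raster$values
  cv <- matrix(classify_hsi(as.numeric(v), classes), nrow(v), ncol(v))
  out <- hsi_raster
  out$values <- cv
  out$name <- "habitat_class"
  attr(out, "classes") <- classes
  out
}

#' Write a P/E curve as CSV
#' @param curve a [pe_curve()].
#' @param path CSV path.
#' @export
write_pe_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
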
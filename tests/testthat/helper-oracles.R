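# Independent oracles and fixture builders used across the suite.  These
# deliberately re-derive quantities by the most direct route available
# (brute-force scans, closed forms, exhaustive enumeration) and never call
# the production code paths they check.

# A stem map of well-separated trees: jittered grid with spacing larger
# than twice the largest crown radius, so every tree is a strict local
# maximum of the rendered surface.
separated_stand <- function(n_side = 10, spacing = 30, hmin = 50, hmax = 90,
                            jitter = 3, seed = 4) {
  set.seed(seed)
  xy <- expand.grid(x = seq(spacing / 2, by = spacing, length.out = n_side),
                    y = seq(spacing / 2, by = spacing, length.out = n_side))
  n <- nrow(xy)
  sm <- data.frame(x = xy$x + stats::runif(n, -jitter, jitter),
                   y = xy$y + stats::runif(n, -jitter, jitter),
                   height_m = stats::runif(n, hmin, hmax))
  side <- spacing * n_side
  attr(sm, "extent") <- c(0, 0, side, side)
  attr(sm, "crown_radius_coeff") <- 0.1
  class(sm) <- c("stem_map", "data.frame")
  sm
}

# O(cells x TAOs) direct scan of a circular-window TAO statistic.
brute_window_stat <- function(taos, grid, stat, height_min, window_area) {
  r <- circle_radius_for_area(window_area)
  out <- matrix(0, grid$nrow, grid$ncol)
  for (i in seq_len(grid$nrow)) for (j in seq_len(grid$ncol)) {
    cx <- grid$xmin + (j - 0.5) * grid$res
    cy <- grid$ymin + (i - 0.5) * grid$res
    d <- sqrt((taos$x - cx)^2 + (taos$y - cy)^2)
    h <- taos$height_m[d <= r & taos$height_m >= height_min]
    out[i, j] <- switch(stat,
      count_density = length(h) / window_area,
      sum = sum(h),
      sd = if (length(h) >= 2) stats::sd(h) else 0,
      min = if (length(h)) min(h) else 0,
      mean = if (length(h)) mean(h) else 0,
      max = if (length(h)) max(h) else 0)
  }
  out
}

# Penalized presence-background objective evaluated directly (vectorised
# over rows of a beta matrix), and a refining direct search over it.
pen_objective <- function(B, Fu, Fa, lambda) {
  B <- matrix(B, ncol = ncol(Fu))
  etaU <- B %*% t(Fu)
  etaA <- B %*% t(Fa)
  lse <- apply(etaA, 1L, function(e) { m <- max(e); m + log(sum(exp(e - m))) })
  rowMeans(etaU) - lse - drop(abs(B) %*% lambda)
}

grid_search_objective <- function(Fu, Fa, lambda, half_width = 5,
                                  n_step = 10, rounds = 5) {
  p <- ncol(Fu)
  ctr <- rep(0, p)
  step <- half_width / n_step
  best <- -Inf
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(p), function(j) ctr[j] + step * (-n_step:n_step))
    g <- as.matrix(do.call(expand.grid, axes))
    v <- pen_objective(g, Fu, Fa, lambda)
    best <- max(v)
    ctr <- g[which.max(v), ]
    step <- step / 5
  }
  best
}

# Exhaustive piecewise-linear breakpoint search, written independently with
# lm() over an explicit hinge basis.
brute_breakpoint_search <- function(x, y, cand, k) {
  combos <- utils::combn(length(cand), k)
  best_sse <- Inf
  best_breaks <- NULL
  for (ci in seq_len(ncol(combos))) {
    br <- cand[combos[, ci]]
    df <- data.frame(y = y, x = x)
    for (b in seq_along(br)) df[[paste0("h", b)]] <- pmax(0, x - br[b])
    f <- stats::lm(y ~ ., data = df)
    sse <- sum(stats::residuals(f)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_breaks <- br
    }
  }
  list(sse = best_sse, breaks = best_breaks)
}

# AUC by explicit pair counting, ties one half.
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# A plain pe_curve object from raw values, bypassing the constructor, for
# breakpoint tests on constructed curves.
toy_pe_curve <- function(centers, pe) {
  curve <- data.frame(center = centers, n_used = 1L, n_available = 1L,
                      p = 1, e = 1, pe = pe, defined = TRUE,
                      smoothed = NA_real_)
  class(curve) <- c("pe_curve", "data.frame")
  curve
}
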
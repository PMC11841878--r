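# Feature expansion for the maximum-entropy model: linear, quadratic,
# product and hinge transforms of the raw covariates, plus the per-feature
# L1 penalties that the regularization multiplier scales.

#' Feature specification
#'
#' @param classes feature classes to build, subset of
#'   `c("linear", "quadratic", "product", "hinge")`.
#' @param n_knots number of quantile knots per covariate for hinge
#'   features (default 50, giving `n_knots - 1` forward and `n_knots - 1`
#'   reverse hinges).
#' @export
feature_spec <- function(classes = c("linear", "quadratic", "product", "hinge"),
                         n_knots = 50) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (n_knots < 2) stop("`n_knots` must be >= 2")
  structure(list(classes = classes, n_knots = as.integer(n_knots)),
            class = "feature_spec")
}

# Freeze the standardisation constants, ranges and hinge knots against the
# available (background) sample: the background characterises the landscape,
# so feature geometry must not drift with the used sample.
make_feature_def <- function(available, spec) {
  X <- as.matrix(available)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  drop <- sd == 0 | !is.finite(sd)
  if (any(drop)) {
    warning(sprintf("dropping zero-variance covariate(s): %s",
                    paste(colnames(X)[drop], collapse = ", ")))
  }
  keep <- which(!drop)
  knots <- lapply(keep, function(j) {
    unname(stats::quantile(X[, j], probs = seq(0, 1, length.out = spec$n_knots)))
  })
  names(knots) <- colnames(X)[keep]
  structure(list(spec = spec, covariates = colnames(X)[keep],
                 mu = mu[keep], sd = sd[keep], knots = knots),
            class = "feature_def")
}

# Expand raw covariates into the model's feature matrix.  Attributes:
# `parent` (covariate name per feature) and `class` (feature class).
expand_features <- function(def, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  miss <- setdiff(def$covariates, colnames(X))
  if (length(miss)) stop(sprintf("missing covariate(s): %s",
                                 paste(miss, collapse = ", ")))
  X <- X[, def$covariates, drop = FALSE]
  Z <- sweep(sweep(X, 2L, def$mu), 2L, def$sd, "/")
  cols <- list(); parents <- character(0); classes <- character(0)
  nms <- character(0)
  p <- length(def$covariates)
  if ("linear" %in% def$spec$classes) {
    for (j in seq_len(p)) {
      cols[[length(cols) + 1L]] <- Z[, j]
      parents <- c(parents, def$covariates[j]); classes <- c(classes, "linear")
      nms <- c(nms, paste0("lin_", def$covariates[j]))
    }
  }
  if ("quadratic" %in% def$spec$classes) {
    for (j in seq_len(p)) {
      cols[[length(cols) + 1L]] <- Z[, j]^2
      parents <- c(parents, def$covariates[j]); classes <- c(classes, "quadratic")
      nms <- c(nms, paste0("quad_", def$covariates[j]))
    }
  }
  if ("product" %in% def$spec$classes && p >= 2L) {
    for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
      cols[[length(cols) + 1L]] <- Z[, a] * Z[, b]
      parents <- c(parents, paste(def$covariates[a], def$covariates[b], sep = ":"))
      classes <- c(classes, "product")
      nms <- c(nms, paste0("prod_", def$covariates[a], "_", def$covariates[b]))
    }
  }
  if ("hinge" %in% def$spec$classes) {
    for (j in seq_len(p)) {
      kn <- def$knots[[def$covariates[j]]]
      lo <- kn[1L]; hi <- kn[length(kn)]
      for (k in kn[-length(kn)]) {
        if (hi - k <= 0) next
        cols[[length(cols) + 1L]] <- pmax(0, X[, j] - k) / (hi - k)
        parents <- c(parents, def$covariates[j]); classes <- c(classes, "hinge")
        nms <- c(nms, sprintf("hf_%s_%.6g", def$covariates[j], k))
      }
      for (k in kn[-1L]) {
        if (k - lo <= 0) next
        cols[[length(cols) + 1L]] <- pmax(0, k - X[, j]) / (k - lo)
        parents <- c(parents, def$covariates[j]); classes <- c(classes, "hinge")
        nms <- c(nms, sprintf("hr_%s_%.6g", def$covariates[j], k))
      }
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- nms
  attr(F, "parent") <- parents
  attr(F, "class") <- classes
  F
}

# Published default per-class base penalty constants, interpolated by the
# number of presence (used) samples; the regularization multiplier scales
# them uniformly.
base_penalty <- function(class, n_used) {
  interp <- function(xs, ys) stats::approx(xs, ys, xout = n_used, rule = 2)$y
  switch(class,
    linear    = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    quadratic = interp(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product   = interp(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.05)),
    hinge     = 0.5,
    stop("unknown feature class"))
}

#' Build expanded feature matrices and per-feature penalties
#'
#' Expands the used and available covariate matrices into model features
#' (linear terms are standardised against the available sample; quadratic
#' and product terms are built from the standardised covariates; hinges sit
#' at `n_knots` equally spaced quantiles of the available distribution,
#' rescaled to \[0, 1\]).  The L1 penalty for feature j is
#' `RM * base(class, n_used) * sd_used(f_j) / sqrt(n_used)`; a feature that
#' is constant over the used sample falls back to its spread over the
#' available sample so the penalty never vanishes by accident.
#'
#' @param used,available raw covariate matrices sharing columns.
#' @param spec a [feature_spec()].
#' @param rm regularization multiplier (> 0, default 2).
#' @return list with `used`, `available` (feature matrices), `lambda`
#'   (penalties), and `def` (the frozen feature definition).
#' @export
build_features <- function(used, available, spec = feature_spec(), rm = 2) {
  if (rm <= 0) stop("`rm` must be positive")
  def <- make_feature_def(available, spec)
  Fu <- expand_features(def, used)
  Fa <- expand_features(def, available)
  n_used <- nrow(Fu)
  sd_u <- apply(Fu, 2L, stats::sd)
  sd_a <- apply(Fa, 2L, stats::sd)
  sd_eff <- ifelse(sd_u > 0, sd_u, sd_a)
  base <- vapply(attr(Fu, "class"), base_penalty, 0, n_used = n_used)
  lambda <- rm * base * sd_eff / sqrt(n_used)
  list(used = Fu, available = Fa, lambda = lambda, def = def, rm = rm)
}
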
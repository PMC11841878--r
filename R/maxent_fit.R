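# Penalized presence-background maximum-entropy fit.  The objective, on
# the per-presence scale, is
#
#   Q(beta) = mean_used(beta' f) - log sum_available exp(beta' f)
#             - sum_j lambda_j |beta_j|
#
# maximised by cyclic coordinate ascent with soft-thresholding (a proximal
# Newton step per coordinate with step halving), which keeps the objective
# monotone non-decreasing and drives sub-threshold coefficients exactly to
# zero.

#' Fit configuration
#'
#' @param rm regularization multiplier (default 2.0, the value the study
#'   design fixed during covariate selection).
#' @param max_iter cap on single-feature updates (default 5000).
#' @param tol relative objective-change convergence tolerance per sweep
#'   (default 1e-5).
#' @param replicates bootstrap replicates (default 10).
#' @param train_frac fraction of used points per bootstrap training set
#'   (default 0.8).
#' @param tau logistic scaling constant (default 0.5; with the entropy
#'   form used here tau enters as `exp(H) * tau / (1 - tau)`, which is
#'   `exp(H)` at the default).
#' @param track record per-covariate objective-improvement credits for
#'   percent-contribution reporting (default TRUE).
#' @param seed integer seed for bootstrap resampling.
#' @export
fit_config <- function(rm = 2.0, max_iter = 5000L, tol = 1e-5,
                       replicates = 10L, train_frac = 0.8, tau = 0.5,
                       track = TRUE, seed = 1L) {
  if (rm <= 0) stop("`rm` must be positive")
  if (train_frac <= 0 || train_frac >= 1) stop("`train_frac` must be in (0, 1)")
  structure(list(rm = rm, max_iter = as.integer(max_iter), tol = tol,
                 replicates = as.integer(replicates), train_frac = train_frac,
                 tau = tau, track = isTRUE(track), seed = as.integer(seed)),
            class = "fit_config")
}

#' Fit the penalized maximum-entropy model on expanded features
#'
#' @param used_features,available_features feature matrices from
#'   [build_features()] (or any numeric matrices sharing columns).
#' @param lambda per-feature L1 penalties (recycled if length 1).
#' @param config a [fit_config()].
#' @param def optional frozen `feature_def`, kept so predictions can be
#'   made from raw covariates.
#' @return a `maxent_model` with coefficients `beta`, background
#'   normalizer `logZ`, background entropy `H` (nats), the penalties,
#'   convergence diagnostics and (when tracking) per-covariate gain
#'   credits.
#' @export
fit_maxent <- function(used_features, available_features, lambda,
                       config = fit_config(), def = NULL) {
  Fu <- as.matrix(used_features); Fa <- as.matrix(available_features)
  if (ncol(Fu) != ncol(Fa)) stop("feature matrices must share columns")
  if (nrow(Fu) < 2L) stop("need at least two used points")
  if (nrow(Fa) < nrow(Fu)) stop("available sample must be at least as large as used")
  p <- ncol(Fu)
  lambda <- rep_len(lambda, p)
  parents <- attr(used_features, "parent") %||% colnames(Fu) %||%
    paste0("f", seq_len(p))
  mu_u <- colMeans(Fu)
  beta <- numeric(p)
  eta <- rep(0, nrow(Fa))          # Fa %*% beta, maintained incrementally
  obj <- -log(nrow(Fa))            # Q(0)
  contrib <- stats::setNames(numeric(length(unique(parents))), unique(parents))
  obj_trace <- obj
  iter <- 0L
  converged <- FALSE
  while (iter < config$max_iter) {
    obj_start <- obj
    for (j in seq_len(p)) {
      if (iter >= config$max_iter) break
      iter <- iter + 1L
      m <- max(eta)
      w <- exp(eta - m)
      sw <- sum(w)
      q <- w / sw
      fj <- Fa[, j]
      mj <- sum(q * fj)
      vj <- sum(q * fj * fj) - mj * mj
      g <- mu_u[j] - mj
      h <- max(vj, 1e-10)
      z <- beta[j] + g / h
      bnew <- sign(z) * max(0, abs(z) - lambda[j] / h)
      d <- bnew - beta[j]
      if (d == 0) next
      # step-halving safeguard: accept only non-decreasing objective moves
      obj_try <- -Inf
      for (half in 0:20) {
        b_try <- beta
        b_try[j] <- beta[j] + d
        obj_try <- sum(mu_u * b_try) - logsumexp(eta + d * fj) -
          sum(lambda * abs(b_try))
        if (obj_try >= obj - 1e-12) break
        d <- d / 2
      }
      if (obj_try >= obj - 1e-12) {
        if (config$track) {
          pj <- parents[j]
          contrib[pj] <- contrib[pj] + max(0, obj_try - obj)
        }
        beta[j] <- beta[j] + d
        eta <- eta + d * fj
        obj <- obj_try
      }
    }
    obj_trace <- c(obj_trace, obj)
    if (abs(obj - obj_start) <= config$tol * (abs(obj_start) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= config$max_iter) {
    # cap reached; expose diagnostics but do not fail -- the cap mirrors the
    # fitting-iteration budget of the study design
    warning(sprintf("iteration cap (%d) reached; last relative change %.3g",
                    config$max_iter,
                    abs(utils::tail(diff(obj_trace), 1)) / (abs(obj) + 1e-10)))
  }
  logZ <- logsumexp(eta)
  q <- exp(eta - logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  structure(list(beta = stats::setNames(beta, colnames(Fu)),
                 logZ = logZ, H = H, lambda = lambda,
                 rm = config$rm, tau = config$tau,
                 parents = parents,
                 feature_classes = attr(used_features, "class"),
                 def = def,
                 n_used = nrow(Fu), n_available = nrow(Fa),
                 iterations = iter, converged = converged,
                 objective = obj, obj_trace = obj_trace,
                 contrib = if (config$track) contrib else NULL),
            class = "maxent_model")
}

#' High-level model fit from raw covariate matrices
#'
#' Convenience wrapper: expands features with [build_features()] and fits
#' with [fit_maxent()], so the returned model predicts directly from raw
#' covariates.
#'
#' @param used,available raw covariate matrices sharing columns.
#' @param spec a [feature_spec()].
#' @param config a [fit_config()]; its `rm` scales the penalties.
#' @export
maxent_hsm <- function(used, available, spec = feature_spec(),
                       config = fit_config()) {
  fb <- build_features(used, available, spec, rm = config$rm)
  fit_maxent(fb$used, fb$available, fb$lambda, config, def = fb$def)
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d features (%d nonzero), RM %.2g, H = %.3f nats\n",
              length(x$beta), sum(x$beta != 0), x$rm, x$H))
  cat(sprintf("  n_used %d, n_available %d, %d iterations, converged: %s\n",
              x$n_used, x$n_available, x$iterations, x$converged))
  invisible(x)
}

model_eta <- function(model, x, features = FALSE) {
  F <- if (features || is.null(model$def)) as.matrix(x) else
    expand_features(model$def, x)
  drop(F %*% model$beta)
}

#' Raw (background-normalized) prediction
#'
#' `exp(beta' f(x) - logZ)`; over the fitting background the raw values sum
#' to one.
#'
#' @param model a fitted `maxent_model`.
#' @param x raw covariate matrix (or feature matrix with
#'   `features = TRUE`).
#' @param features set TRUE when `x` is already a feature matrix.
#' @export
predict_raw <- function(model, x, features = FALSE) {
  exp(model_eta(model, x, features) - model$logZ)
}

#' Scaled logistic prediction (HSI)
#'
#' `HSI = r c / (1 + r c)` with `r` the raw prediction and
#' `c = exp(H) tau / (1 - tau)`; at the default `tau = 0.5` this is the
#' classic `r exp(H) / (1 + r exp(H))` scaling, strictly increasing in the
#' raw output and equal to 0.5 everywhere for the null model.
#'
#' @inheritParams predict_raw
#' @export
predict_logistic <- function(model, x, features = FALSE) {
  r <- predict_raw(model, x, features)
  c0 <- exp(model$H) * model$tau / (1 - model$tau)
  r * c0 / (1 + r * c0)
}

#' Regularized training gain
#'
#' Mean used log raw output plus `log(n_available)` minus the penalty --
#' the likelihood improvement, in nats, of the model over the uniform
#' background distribution; 0 for the null model, and `exp(gain)` is the
#' per-observation likelihood-ratio factor.
#'
#' @param model a fitted `maxent_model`.
#' @param used_features feature (or raw covariate) rows of the used sample.
#' @param features TRUE when already expanded.
#' @param penalized subtract the L1 penalty (TRUE for training gain; set
#'   FALSE for test gain on held-out data).
#' @export
gain <- function(model, used_features, features = FALSE, penalized = TRUE) {
  lr <- log(predict_raw(model, used_features, features))
  g <- mean(lr) + log(model$n_available)
  if (penalized) g <- g - sum(model$lambda * abs(model$beta))
  g
}

#' Akaike information criterion of a fitted model
#'
#' `k` is the number of nonzero coefficients, `lnL` the summed used log
#' raw output, and `AIC = 2k - 2 lnL` (the niche-modelling convention).
#'
#' @inheritParams gain
#' @return list with `k`, `lnL`, `aic`.
#' @export
aic <- function(model, used_features, features = FALSE) {
  k <- sum(model$beta != 0)
  lnL <- sum(log(predict_raw(model, used_features, features)))
  list(k = k, lnL = lnL, aic = 2 * k - 2 * lnL)
}

#' Arithmetic AIC helper
#'
#' `2k - 2 lnL` for externally supplied parameter count and log-likelihood
#' (e.g. replicate averages).
#' @param k parameter count (may be a replicate average, hence fractional).
#' @param lnL log-likelihood.
#' @export
aic_value <- function(k, lnL) 2 * k - 2 * lnL

#' Bootstrap-replicate fits
#'
#' Per replicate, draws `round(train_frac * n_used)` used points with
#' replacement (a bootstrap training set); points never drawn form the
#' held-out set on which test gain and AUC are evaluated.  Replicate
#' assignments are a pure function of `config$seed`.
#'
#' @param used,available raw covariate matrices.
#' @param spec a [feature_spec()].
#' @param config a [fit_config()].
#' @return list with `models` (per replicate), `stats` (data.frame of
#'   per-replicate train gain, test gain, test AUC, k, AIC) and `median`
#'   summaries.
#' @export
bootstrap_fit <- function(used, available, spec = feature_spec(),
                          config = fit_config()) {
  n <- nrow(used)
  n_train <- round(config$train_frac * n)
  if (n_train < 2L || n_train >= n) stop("too few used points to split")
  draws <- with_seed(config$seed, {
    lapply(seq_len(config$replicates), function(i)
      sample.int(n, n_train, replace = TRUE))
  })
  models <- vector("list", config$replicates)
  rows <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    tr <- draws[[i]]
    te <- setdiff(seq_len(n), unique(tr))
    m <- maxent_hsm(used[tr, , drop = FALSE], available, spec, config)
    a <- aic(m, used[tr, , drop = FALSE])
    test_gain <- if (length(te)) {
      gain(m, used[te, , drop = FALSE], penalized = FALSE)
    } else NA_real_
    test_auc <- if (length(te)) {
      auc(predict_raw(m, used[te, , drop = FALSE]),
          predict_raw(m, available))
    } else NA_real_
    models[[i]] <- m
    rows[[i]] <- data.frame(replicate = i, n_train = length(tr),
                            n_test = length(te),
                            train_gain = gain(m, used[tr, , drop = FALSE]),
                            test_gain = test_gain, test_auc = test_auc,
                            k = a$k, lnL = a$lnL, aic = a$aic)
  }
  stats <- do.call(rbind, rows)
  list(models = models, stats = stats,
       median = vapply(stats[, -1L], stats::median, 0, na.rm = TRUE))
}
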
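# The four-phase covariate-selection protocol: correlation screening,
# per-covariate strength measures (percent contribution, permutation
# importance, jackknife gains), enumeration of uncorrelated candidate
# models, bootstrap-AIC comparison, and the regularization-multiplier
# sweep.

#' Pairwise correlation screen
#'
#' Continuous pairs get squared Pearson correlation; categorical pairs get
#' Cramer's V from the (uncorrected) chi-square statistic; mixed pairs get
#' V after decile-binning the continuous member.  Covariates whose
#' statistic strictly exceeds the threshold are linked, and the connected
#' components of that graph form the correlated groups.
#'
#' @param x design matrix (data.frame or matrix), one column per covariate.
#' @param kinds `"continuous"` or `"categorical"` per covariate (recycled).
#' @param threshold correlation threshold (default 0.65; "exceeds" is
#'   strict).
#' @return a `correlation_report`: `r2` and `v` matrices, `statistic`
#'   (the applicable measure per pair), `groups` (list partitioning the
#'   covariates), `threshold`.
#' @export
correlation_screen <- function(x, kinds = "continuous", threshold = 0.65) {
  x <- as.data.frame(x)
  p <- ncol(x)
  if (p < 2L) stop("need at least two covariates")
  kinds <- rep_len(kinds, p)
  nms <- colnames(x)
  stat <- matrix(0, p, p, dimnames = list(nms, nms))
  diag(stat) <- 1
  r2 <- stat; v <- stat
  decile_bin <- function(z) {
    br <- unique(stats::quantile(z, probs = seq(0, 1, 0.1)))
    if (length(br) < 2L) return(factor(rep(1L, length(z))))
    cut(z, breaks = br, include.lowest = TRUE)
  }
  cramers_v <- function(a, b) {
    tab <- table(a, b)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (min(dim(tab)) < 2L) return(0)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    unname(sqrt(chi / (sum(tab) * (min(dim(tab)) - 1L))))
  }
  for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
    if (kinds[a] == "continuous" && kinds[b] == "continuous") {
      sa <- stats::sd(x[[a]]); sb <- stats::sd(x[[b]])
      if (sa == 0 || sb == 0) {
        warning(sprintf("constant column in pair (%s, %s); R^2 set to 0",
                        nms[a], nms[b]))
        s <- 0
      } else s <- stats::cor(x[[a]], x[[b]])^2
      r2[a, b] <- r2[b, a] <- s
    } else {
      fa <- if (kinds[a] == "continuous") decile_bin(x[[a]]) else factor(x[[a]])
      fb <- if (kinds[b] == "continuous") decile_bin(x[[b]]) else factor(x[[b]])
      s <- cramers_v(fa, fb)
      v[a, b] <- v[b, a] <- s
    }
    stat[a, b] <- stat[b, a] <- s
  }
  # connected components over edges strictly exceeding the threshold
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
    if (stat[a, b] > threshold) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(p), find, 0L)
  groups <- unname(split(nms, roots))
  groups <- groups[order(vapply(groups, function(g) match(g[1L], nms), 0L))]
  structure(list(r2 = r2, v = v, statistic = stat, kinds = kinds,
                 threshold = threshold, groups = groups),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d covariates, threshold %.2f, %d group(s)\n",
              nrow(x$statistic), x$threshold, length(x$groups)))
  for (g in x$groups) if (length(g) > 1L) cat("  correlated:", paste(g, collapse = " ~ "), "\n")
  invisible(x)
}

#' Permutation importance
#'
#' For each covariate, permutes its values jointly across the used and
#' available rows, recomputes training AUC with the fixed fitted model, and
#' reports the mean AUC drop normalised so importances sum to 100.
#'
#' @param model a fitted `maxent_model` (carrying its feature definition).
#' @param used,available raw covariate matrices used for fitting.
#' @param n_perm permutations per covariate (default 10).
#' @param seed RNG seed.
#' @return named vector of importances summing to 100 (all-zero vector if
#'   no permutation changes AUC).
#' @export
permutation_importance <- function(model, used, available, n_perm = 10,
                                   seed = 1L) {
  if (is.null(model$def)) stop("model must carry a feature definition")
  covs <- model$def$covariates
  base_auc <- auc(predict_raw(model, used), predict_raw(model, available))
  n_u <- nrow(used); n_a <- nrow(available)
  drops <- stats::setNames(numeric(length(covs)), covs)
  with_seed(seed, {
    for (cv in covs) {
      dd <- 0
      for (r in seq_len(n_perm)) {
        pooled <- c(used[, cv], available[, cv])
        pooled <- pooled[sample.int(length(pooled))]
        up <- used; ap <- available
        up[, cv] <- pooled[seq_len(n_u)]
        ap[, cv] <- pooled[n_u + seq_len(n_a)]
        a <- auc(predict_raw(model, up), predict_raw(model, ap))
        dd <- dd + max(0, base_auc - a)
      }
      drops[cv] <- dd / n_perm
    }
  })
  s <- sum(drops)
  if (s == 0) drops else 100 * drops / s
}

#' Percent contribution
#'
#' Maxent-style path-dependent attribution: every accepted coordinate
#' update's objective improvement during fitting is credited to the updated
#' feature's parent covariate; totals are normalised to 100.  Requires a
#' model fitted with `track = TRUE` (the default).
#'
#' @param model a fitted `maxent_model`.
#' @return named vector summing to 100 over the model's covariates.
#' @export
percent_contribution <- function(model) {
  if (is.null(model$contrib)) {
    stop("no fit trace recorded; refit with fit_config(track = TRUE)")
  }
  # credit product features half to each parent
  covs <- if (!is.null(model$def)) model$def$covariates else
    unique(unlist(strsplit(names(model$contrib), ":")))
  out <- stats::setNames(numeric(length(covs)), covs)
  for (nm in names(model$contrib)) {
    parts <- strsplit(nm, ":")[[1L]]
    for (pp in parts) out[pp] <- out[pp] + model$contrib[[nm]] / length(parts)
  }
  s <- sum(out)
  if (s == 0) out else 100 * out / s
}

#' Jackknife gains
#'
#' Fits, for each covariate, the model using only that covariate and the
#' model using all covariates but that one, reporting regularized training
#' gain (and test gain over bootstrap held-out points when
#' `replicates > 0`).
#'
#' @param used,available raw covariate matrices (>= 2 columns).
#' @param spec a [feature_spec()].
#' @param config a [fit_config()].
#' @param threshold advancement rule on the only-covariate gain (default
#'   2.5); reported, not enforced.
#' @return data.frame with one row per covariate: `only_gain`,
#'   `without_gain`, `full_gain`, `advance`.
#' @export
jackknife_gains <- function(used, available, spec = feature_spec(),
                            config = fit_config(), threshold = 2.5) {
  covs <- colnames(used)
  if (length(covs) < 2L) stop("need at least two covariates")
  fit_gain <- function(cols) {
    m <- maxent_hsm(used[, cols, drop = FALSE],
                    available[, cols, drop = FALSE], spec, config)
    gain(m, used[, cols, drop = FALSE])
  }
  full <- fit_gain(covs)
  rows <- lapply(covs, function(cv) {
    data.frame(covariate = cv,
               only_gain = fit_gain(cv),
               without_gain = fit_gain(setdiff(covs, cv)),
               full_gain = full)
  })
  out <- do.call(rbind, rows)
  out$advance <- out$only_gain >= threshold
  out
}

#' Enumerate candidate models of pairwise-uncorrelated covariates
#'
#' Takes exactly one covariate from every correlated group (Cartesian
#' selection) together with all singleton covariates; candidates are
#' deduplicated and returned in deterministic lexicographic order.
#'
#' @param covariates covariates to consider (default: all in the report).
#' @param report a `correlation_report`.
#' @return list of character vectors, one per candidate model.
#' @export
enumerate_uncorrelated_models <- function(covariates = NULL, report) {
  stopifnot(inherits(report, "correlation_report"))
  all_cov <- rownames(report$statistic)
  covariates <- covariates %||% all_cov
  groups <- lapply(report$groups, intersect, x = covariates)
  groups <- groups[vapply(groups, length, 0L) > 0L]
  if (!length(groups)) return(list())
  picks <- expand.grid(groups, stringsAsFactors = FALSE)
  cands <- unique(lapply(seq_len(nrow(picks)), function(i) {
    sort(unname(unlist(picks[i, ])))
  }))
  cands[order(vapply(cands, paste, "", collapse = "|"))]
}

#' Bootstrap-AIC model comparison
#'
#' Fits every candidate covariate set on each of `replicates` bootstrap
#' training resamples of the used points (identical resamples across
#' candidates so streams are comparable), computes AIC on the full used
#' sample, and ranks candidates by median AIC.
#'
#' @param candidates list of covariate-name vectors.
#' @param used,available raw covariate matrices.
#' @param spec a [feature_spec()].
#' @param config a [fit_config()] (its `replicates` and `seed` drive the
#'   resampling).
#' @return list with `table` (per-candidate median/quartiles of AIC,
#'   ranked), `aic` (replicate-by-candidate matrix) and `best` (covariates
#'   of the lowest-median candidate).
#' @export
bootstrap_aic_compare <- function(candidates, used, available,
                                  spec = feature_spec(), config = fit_config()) {
  if (!length(candidates)) stop("need at least one candidate")
  n <- nrow(used)
  n_train <- round(config$train_frac * n)
  draws <- with_seed(config$seed, {
    lapply(seq_len(config$replicates), function(i)
      sample.int(n, n_train, replace = TRUE))
  })
  aic_mat <- matrix(NA_real_, nrow = config$replicates, ncol = length(candidates))
  kmat <- aic_mat; lmat <- aic_mat
  for (ci in seq_along(candidates)) {
    cols <- candidates[[ci]]
    for (ri in seq_len(config$replicates)) {
      m <- maxent_hsm(used[draws[[ri]], cols, drop = FALSE],
                      available[, cols, drop = FALSE], spec, config)
      a <- aic(m, used[, cols, drop = FALSE])
      aic_mat[ri, ci] <- a$aic; kmat[ri, ci] <- a$k; lmat[ri, ci] <- a$lnL
    }
  }
  colnames(aic_mat) <- vapply(candidates, paste, "", collapse = "+")
  qs <- apply(aic_mat, 2L, stats::quantile,
              probs = c(0.1, 0.25, 0.5, 0.75, 0.9))
  tab <- data.frame(model = colnames(aic_mat),
                    mean_k = colMeans(kmat), mean_lnL = colMeans(lmat),
                    mean_aic = colMeans(aic_mat),
                    q10 = qs[1L, ], q25 = qs[2L, ], median_aic = qs[3L, ],
                    q75 = qs[4L, ], q90 = qs[5L, ], row.names = NULL)
  ord <- order(tab$median_aic)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  list(table = tab, aic = aic_mat, best = candidates[[ord[1L]]])
}

#' Regularization-multiplier sweep
#'
#' Runs the bootstrap-AIC comparison of one covariate set across a grid of
#' regularization multipliers (default 1.0 to 5.0 in steps of 0.5) and
#' returns the multiplier with lowest median AIC along with the full
#' summary table (per RM: mean parameter count, mean log-likelihood, mean
#' AIC, delta AIC to the best mean).
#'
#' @param covariates covariate names of the model to tune.
#' @param used,available raw covariate matrices.
#' @param rms multiplier grid.
#' @param spec a [feature_spec()].
#' @param config a [fit_config()] (its `rm` is overridden per grid value).
#' @return list with `best_rm`, `table`, `aic` matrix (replicate x RM).
#' @export
rm_sweep <- function(covariates, used, available,
                     rms = seq(1, 5, by = 0.5),
                     spec = feature_spec(), config = fit_config()) {
  if (!length(rms)) stop("`rms` must be nonempty")
  rows <- list(); aics <- list()
  medians <- numeric(length(rms))
  for (i in seq_along(rms)) {
    cfg <- config
    cfg$rm <- rms[i]
    cmp <- bootstrap_aic_compare(list(covariates), used, available, spec, cfg)
    rows[[i]] <- data.frame(rm = rms[i],
                            mean_k = cmp$table$mean_k,
                            mean_lnL = cmp$table$mean_lnL,
                            mean_aic = cmp$table$mean_aic,
                            median_aic = cmp$table$median_aic)
    aics[[i]] <- cmp$aic[, 1L]
    medians[i] <- cmp$table$median_aic
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$mean_aic), , drop = FALSE]
  tab$delta_aic <- tab$mean_aic - tab$mean_aic[1L]
  aic_mat <- do.call(cbind, aics)
  colnames(aic_mat) <- sprintf("rm_%.1f", rms)
  list(best_rm = rms[which.min(medians)], table = tab, aic = aic_mat)
}

#' Simulate a used/available design for selection-protocol checks
#'
#' Draws an available sample of three signal covariates (named after the
#' final-model trio) and three noise covariates, each noise covariate
#' correlated with one signal covariate at correlation `rho`; used rows are
#' drawn from the available pool with probability proportional to
#' `exp(effect * (z1 + z2 + z3))`, i.e. the generating model is linear in
#' the three signal covariates only.
#'
#' @param n_used,n_available sample sizes.
#' @param effect linear selection strength per signal covariate (default 1).
#' @param rho signal-noise correlation (default 0.85, squared 0.72, above
#'   the 0.65 screening threshold).
#' @param seed RNG seed.
#' @return list with `used`, `available` covariate matrices and
#'   `signal`/`noise` name vectors.
#' @export
simulate_selection_design <- function(n_used = 250, n_available = 1500,
                                      effect = 1, rho = 0.85, seed = 1L) {
  with_seed(seed, {
    sig <- c("density_ge60_5ac", "sumht_ge50_5ac", "sdht_ge50_5ac")
    noi <- paste0("noise", 1:3)
    Z <- matrix(stats::rnorm(n_available * 3L), ncol = 3L)
    N <- rho * Z + sqrt(1 - rho^2) * matrix(stats::rnorm(n_available * 3L), ncol = 3L)
    avail <- cbind(Z, N)
    colnames(avail) <- c(sig, noi)
    w <- exp(effect * rowSums(Z))
    idx <- sample.int(n_available, n_used, replace = TRUE, prob = w)
    list(used = avail[idx, , drop = FALSE], available = avail,
         signal = sig, noise = noi)
  })
}
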
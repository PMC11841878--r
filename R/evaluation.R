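# Model evaluation: used-vs-background ROC/AUC, thresholded confusion
# matrix, sensitivity, positive predictive value, Cohen's kappa, and
# marginal response curves.

#' Thresholded confusion matrix
#'
#' Positives are predictions at or above the threshold (the habitat
#' boundary is inclusive, so the low-class lower bound itself counts as
#' habitat).  Negatives are the available points *not* labelled used --
#' the two-sample bookkeeping in which the used sample is a subset of the
#' available sample, so `TP + FN` is the used count and `FP + TN` the
#' non-used available count.
#'
#' @param used_hsi HSI values of the used points (nonempty).
#' @param available_hsi HSI values of the full available sample
#'   (including the used points) when `used_included = TRUE`, or of the
#'   non-used points only when `FALSE`.
#' @param threshold habitat threshold in \[0, 1\].
#' @param used_included does `available_hsi` contain the used points?
#'   If TRUE the used values are removed count-wise before forming the
#'   negatives.
#' @return a `confusion_matrix`: list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(used_hsi, available_hsi, threshold,
                      used_included = FALSE) {
  if (!length(used_hsi)) stop("used sample is empty")
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  tp <- sum(used_hsi >= threshold)
  fn <- length(used_hsi) - tp
  pos_avail <- sum(available_hsi >= threshold)
  n_avail <- length(available_hsi)
  if (used_included) {
    pos_avail <- pos_avail - tp
    n_avail <- n_avail - length(used_hsi)
  }
  fp <- pos_avail
  tn <- n_avail - pos_avail
  if (fp < 0 || tn < 0) stop("available sample inconsistent with used sample")
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn),
                 threshold = threshold),
            class = "confusion_matrix")
}

confusion_matrix <- function(tp, fp, fn, tn, threshold = NA_real_) {
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn),
                 threshold = threshold),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix (threshold %s):\n",
              format(x$threshold)))
  cat(sprintf("  TP %g  FP %g\n  FN %g  TN %g\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity: TP / (TP + FN)
#' @param cm a `confusion_matrix`.
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn <= 0) stop("no used points: sensitivity undefined")
  cm$tp / (cm$tp + cm$fn)
}

#' Positive predictive value: TP / (TP + FP)
#' @param cm a `confusion_matrix`.
#' @export
ppv <- function(cm) {
  if (cm$tp + cm$fp <= 0) stop("no positive predictions: PPV undefined")
  cm$tp / (cm$tp + cm$fp)
}

#' Cohen's kappa of a 2x2 confusion matrix
#'
#' `2 (TP TN - FN FP) / ((TP + FP)(FP + TN) + (TP + FN)(FN + TN))`,
#' the closed form of chance-corrected agreement for a 2x2 table.
#'
#' @param cm a `confusion_matrix`.
#' @return kappa in \[-1, 1\]; the numerator and denominator are attached
#'   as attributes for exact-arithmetic inspection.
#' @export
kappa_statistic <- function(cm) {
  num <- 2 * (cm$tp * cm$tn - cm$fn * cm$fp)
  den <- (cm$tp + cm$fp) * (cm$fp + cm$tn) + (cm$tp + cm$fn) * (cm$fn + cm$tn)
  if (den == 0) stop("degenerate confusion matrix: kappa undefined")
  structure(num / den, numerator = num, denominator = den)
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' The probability that a randomly chosen used score exceeds a randomly
#' chosen available (non-used) score, with ties counted one half.
#'
#' @param pos scores of the used sample.
#' @param neg scores of the available (background) sample.
#' @export
auc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both samples must be nonempty")
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (as.numeric(length(pos)) * length(neg))
}

#' Evaluation metrics report
#'
#' @param used_hsi,available_hsi HSI samples (available excluding used
#'   unless `used_included`).
#' @param threshold habitat threshold.
#' @param used_included see [confusion()].
#' @return list with `auc`, `sensitivity`, `ppv`, `kappa`, `threshold`,
#'   `cm`.
#' @export
evaluate_model <- function(used_hsi, available_hsi, threshold,
                           used_included = FALSE) {
  cm <- confusion(used_hsi, available_hsi, threshold, used_included)
  neg <- if (used_included) available_hsi else available_hsi
  list(auc = auc(used_hsi, neg),
       sensitivity = sensitivity(cm),
       ppv = ppv(cm),
       kappa = as.numeric(kappa_statistic(cm)),
       threshold = threshold,
       cm = cm)
}

#' Marginal response curve
#'
#' Varies one covariate over its available-sample range at `n_points`
#' evenly spaced values while holding every other covariate at its
#' available-sample mean, and reports the logistic HSI.  With a list of
#' bootstrap replicate models a mean and standard-deviation band over
#' replicates is returned.
#'
#' @param model a fitted `maxent_model` carrying its feature definition.
#' @param available raw available covariate matrix (defines range and
#'   means).
#' @param covariate covariate name.
#' @param n_points grid size (default 100).
#' @param replicates optional list of replicate models.
#' @return data.frame with `value`, `hsi` (and `hsi_sd` with replicates).
#' @export
marginal_response <- function(model, available, covariate, n_points = 100,
                              replicates = NULL) {
  if (is.null(model$def)) stop("model must carry a feature definition")
  covs <- model$def$covariates
  if (!covariate %in% covs) stop(sprintf("unknown covariate '%s'", covariate))
  rng <- range(available[, covariate])
  grid <- seq(rng[1L], rng[2L], length.out = n_points)
  X <- matrix(rep(colMeans(available[, covs, drop = FALSE]), each = n_points),
              nrow = n_points, dimnames = list(NULL, covs))
  X[, covariate] <- grid
  hsi <- predict_logistic(model, X)
  out <- data.frame(value = grid, hsi = hsi)
  if (!is.null(replicates) && length(replicates)) {
    H <- vapply(replicates, function(m) predict_logistic(m, X),
                numeric(n_points))
    out$hsi <- rowMeans(H)
    out$hsi_sd <- apply(H, 1L, stats::sd)
  }
  out
}
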
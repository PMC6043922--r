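#' Fit a random-forest classifier
#'
#' Thin, seeded wrapper around [randomForest::randomForest()]: 500
#' bootstrap-resampled classification trees with random feature subsetting
#' (`sqrt(d)` candidate features per split). Predicted probabilities are
#' the fraction of trees voting for the positive class.
#'
#' @param x Numeric feature matrix or data frame (no missing values:
#'   masked features are imputed upstream).
#' @param y Binary labels: logical, 0/1 or a two-level factor whose second
#'   level is the positive class.
#' @param n_trees Number of trees.
#' @param mtry Features tried per split; default `sqrt(d)` rounded down.
#' @param seed Integer seed making the fit deterministic.
#' @return An object of class `spatial_rf` wrapping the forest.
#' @export
fit_random_forest <- function(x, y, n_trees = 500, mtry = NULL, seed = 1) {
  x <- as.matrix(x)
  y <- .as_binary_factor(y)
  if (length(unique(y)) < 2) {
    abort("Labels contain a single class; a classifier cannot be fitted.")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry)
  structure(list(forest = fit, levels = levels(y), n_trees = n_trees,
                 seed = seed, features = colnames(x)),
            class = "spatial_rf")
}

#' @export
print.spatial_rf <- function(x, ...) {
  cat(sprintf("<spatial_rf> %d trees, %d features, OOB error %.3f\n",
              x$n_trees, length(x$features),
              mean(x$forest$err.rate[x$n_trees, "OOB"])))
  invisible(x)
}

#' Predicted positive-class probabilities of a `spatial_rf`
#'
#' @param object A `spatial_rf` model.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of tree-vote fractions for the positive class.
#' @export
predict.spatial_rf <- function(object, newdata, ...) {
  p <- predict(object$forest, as.matrix(newdata), type = "prob")
  unname(p[, object$levels[2]])
}

.as_binary_factor <- function(y) {
  if (is.logical(y)) return(factor(y, levels = c(FALSE, TRUE),
                                   labels = c("neg", "pos")))
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    return(factor(y, levels = c(0, 1), labels = c("neg", "pos")))
  }
  y <- as.factor(y)
  if (nlevels(y) != 2) abort("Labels must be binary.")
  y
}

#' Leave-one-group-out cross-validated probabilities
#'
#' For each held-out group (a single image, or all images of a patient), a
#' model is fitted on the remaining groups and predicts the held-out
#' probabilities, so every image receives exactly one out-of-fold
#' probability. Any fit-time preprocessing supplied via `preprocess` (e.g.
#' an MFPCA basis) is refitted inside each training fold, never on the
#' full data.
#'
#' A training fold collapsing to a single class yields the training-class
#' prevalence as prediction, with a warning.
#'
#' @param features Numeric feature matrix (rows = images).
#' @param labels Binary labels aligned to rows.
#' @param groups Fold identifiers aligned to rows (image ids for
#'   leave-one-image-out, patient ids for leave-one-patient-out).
#' @param n_trees,seed Forest parameters; per-fold seeds are derived from
#'   `seed`.
#' @param preprocess Optional `function(train_x, test_x, train_idx)`
#'   returning `list(train =, test =)` transformed matrices.
#' @return Numeric vector of out-of-fold probabilities aligned to rows.
#' @export
loocv_predict <- function(features, labels, groups, n_trees = 500,
                          seed = 1, preprocess = NULL) {
  features <- as.matrix(features)
  y <- .as_binary_factor(labels)
  stopifnot(nrow(features) == length(y), length(groups) == length(y))
  folds <- unique(groups)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, length(folds))
  probs <- rep(NA_real_, length(y))
  for (f in seq_along(folds)) {
    test <- which(groups == folds[f])
    train <- which(groups != folds[f])
    probs[test] <- .fit_predict_fold(features, y, train, test,
                                     n_trees, fold_seeds[f], preprocess)
  }
  probs
}

.fit_predict_fold <- function(features, y, train, test, n_trees, seed,
                              preprocess) {
  xtr <- features[train, , drop = FALSE]
  xte <- features[test, , drop = FALSE]
  if (!is.null(preprocess)) {
    tp <- preprocess(xtr, xte, train)
    xtr <- tp$train; xte <- tp$test
  }
  ytr <- y[train]
  if (length(unique(ytr)) < 2) {
    warn("Training fold has a single class; predicting its prevalence.")
    return(rep(mean(ytr == levels(y)[2]), length(test)))
  }
  fit <- fit_random_forest(xtr, ytr, n_trees = n_trees, seed = seed)
  predict(fit, xte)
}

#' Average member predictions into an ensemble
#'
#' Unweighted elementwise arithmetic mean of aligned probability vectors.
#'
#' @param prob_vectors List of equal-length numeric vectors (or a matrix
#'   with one column per member). Named vectors must agree on their names
#'   (image order).
#' @param weights Optional member weights (normalised internally).
#' @return Numeric probability vector.
#' @examples
#' ensemble_combine(list(c(0.2), c(0.6)))  # 0.4
#' @export
ensemble_combine <- function(prob_vectors, weights = NULL) {
  if (is.matrix(prob_vectors)) {
    prob_vectors <- lapply(seq_len(ncol(prob_vectors)),
                           function(j) prob_vectors[, j])
  }
  lens <- vapply(prob_vectors, length, integer(1))
  if (length(unique(lens)) != 1) {
    abort("Member probability vectors have different lengths.")
  }
  nms <- lapply(prob_vectors, names)
  nms <- nms[!vapply(nms, is.null, logical(1))]
  if (length(nms) > 1 &&
      any(vapply(nms[-1], function(n) !identical(n, nms[[1]]), logical(1)))) {
    abort("Member probability vectors are not aligned (names differ).")
  }
  m <- do.call(cbind, prob_vectors)
  weights <- weights %||% rep(1, ncol(m))
  stopifnot(length(weights) == ncol(m), all(weights >= 0), sum(weights) > 0)
  drop(m %*% (weights / sum(weights)))
}

#' ROC curve and AUC of predicted probabilities
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen positive
#' outranks a randomly chosen negative, ties counted one half (computed
#' from midranks). The ROC curve is the step function over the unique
#' score thresholds.
#'
#' @param probabilities Numeric scores (higher = more positive).
#' @param labels Binary labels.
#' @return A list with elements `auc` and `roc` (tibble with columns
#'   `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_auc <- function(probabilities, labels) {
  y <- .as_binary_factor(labels)
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  rk <- rank(probabilities)  # midranks handle ties at 1/2
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  roc <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(probabilities[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(probabilities[!pos] >= t), numeric(1))
  )
  list(auc = auc, roc = roc)
}

#' Confidence interval for a classification AUC
#'
#' `method = "delong"` uses the asymptotic DeLong variance of the
#' Mann-Whitney statistic and a normal interval truncated to `[0, 1]`;
#' `method = "bootstrap"` uses stratified resampling with a percentile
#' interval.
#'
#' @inheritParams roc_auc
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return Numeric vector `c(low, high)` with attributes `level`, `method`
#'   and `auc`.
#' @export
auc_ci <- function(probabilities, labels, method = c("delong", "bootstrap"),
                   level = 0.95, n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  y <- .as_binary_factor(labels)
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  auc <- roc_auc(probabilities, y)$auc
  if (method == "delong") {
    v <- .delong_var(probabilities, y)
    if (v <= 0) {
      warn("Degenerate DeLong variance; returning a zero-width interval.")
      ci <- c(auc, auc)
    } else {
      z <- qnorm(1 - (1 - level) / 2)
      ci <- c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
    }
  } else {
    set.seed(seed)
    ipos <- which(y == levels(y)[2]); ineg <- which(y != levels(y)[2])
    reps <- vapply(seq_len(n_boot), function(b) {
      ii <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
      roc_auc(probabilities[ii], y[ii])$auc
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c((1 - level) / 2,
                                         1 - (1 - level) / 2)))
  }
  structure(ci, level = level, method = method, auc = auc)
}

# DeLong variance of the AUC via pROC's implementation
.delong_var <- function(probabilities, y) {
  roc <- pROC::roc(response = y, predictor = as.numeric(probabilities),
                   levels = levels(y), direction = "<", quiet = TRUE)
  # pROC warns when AUC == 1; the zero-variance case is handled by callers
  suppressWarnings(as.numeric(pROC::var(roc, method = "delong")))
}

#' One-sided test of AUC against random chance
#'
#' Tests whether the observed AUC exceeds 0.5 using the DeLong variance of
#' the Mann-Whitney statistic (normal approximation).
#'
#' @inheritParams roc_auc
#' @return A list with `auc`, `z` and one-sided `p_value` for AUC > 0.5.
#' @export
significance_vs_chance <- function(probabilities, labels) {
  y <- .as_binary_factor(labels)
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  auc <- roc_auc(probabilities, y)$auc
  v <- .delong_var(probabilities, y)
  if (v <= 0) {
    warn("Degenerate DeLong variance in significance test.")
    z <- if (auc > 0.5) Inf else if (auc < 0.5) -Inf else 0
  } else {
    z <- (auc - 0.5) / sqrt(v)
  }
  list(auc = auc, z = z, p_value = pnorm(z, lower.tail = FALSE))
}
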
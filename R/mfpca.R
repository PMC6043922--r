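#' Two-step multivariate functional PCA of the bin-AUC block
#'
#' Compresses the P x K bin-area representation of P correlated G-cross
#' curves into a small number k of uncorrelated scores while retaining a
#' prescribed fraction of the variance.
#'
#' Step 1 (univariate FPCA, per interaction): each interaction's K bin
#' columns are centred (column means computed over unmasked rows) and its
#' K x K covariance eigendecomposed with uniform quadrature weights;
#' univariate components with eigenvalue above `1e-12` times the leading
#' one are retained essentially losslessly, so the variance cut happens
#' only in step 2. Step 2 (multivariate combination): the stacked
#' univariate score vectors of all interactions are jointly
#' eigendecomposed; multivariate scores are the projections onto these
#' orthonormal combination weight vectors, and `k` is the smallest number
#' of leading components whose cumulative eigenvalue fraction reaches
#' `threshold`. Eigenvector signs are fixed so the largest-magnitude entry
#' is positive.
#'
#' @param x Numeric matrix or feature tibble holding the bin-AUC block with
#'   `P * K` columns in interaction-major order (a `spatial_features`
#'   object may be passed directly; its `bin_*` columns and mask are
#'   extracted).
#' @param P,K Number of interactions and bins per interaction. Inferred
#'   from the attached config when `x` is a `spatial_features` tibble.
#' @param threshold Fraction of stacked-score variance the retained
#'   components must explain (default 0.95).
#' @param fixed_k Optional integer overriding the threshold rule, to pin
#'   the score dimension to a preset value.
#' @param mask Optional logical matrix (same shape as the block): entries
#'   flagged TRUE are excluded from the centring means and treated as
#'   missing-at-the-mean.
#' @return An object of class `mfpca` with elements `means`, `elements`
#'   (per-interaction eigenfunctions/eigenvalues), `weights` (combination
#'   weight matrix), `eigenvalues` (multivariate), `cum_var`, `k`,
#'   `threshold`, `scores` (training scores, n x k) and bookkeeping fields.
#' @examples
#' set.seed(1)
#' z <- rnorm(30)
#' X <- outer(z, seq_len(12))          # rank-1 block, P = 3, K = 4
#' fit <- mfpca(X, P = 3, K = 4)
#' fit$k                               # 1
#' @export
mfpca <- function(x, P = NULL, K = NULL, threshold = 0.95, fixed_k = NULL,
                  mask = NULL) {
  if (inherits(x, "spatial_features")) {
    cfg <- attr(x, "config", exact = TRUE)
    P <- P %||% cfg$P
    K <- K %||% cfg$K
    cols <- .bin_columns(x)
    mask <- mask %||% .feature_mask(x)[, cols, drop = FALSE]
    x <- as.matrix(as_tibble(x)[cols])
  }
  x <- as.matrix(x)
  if (is.null(P) || is.null(K)) abort("`P` and `K` must be given.")
  if (ncol(x) != P * K) {
    abort(sprintf("Block has %d columns; expected P * K = %d.",
                  ncol(x), P * K))
  }
  n <- nrow(x)
  if (n < 3) abort("MFPCA needs at least 3 images.")
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(mask)) mask <- matrix(FALSE, n, ncol(x))

  # step 1: per-element centring + eigendecomposition
  elements <- vector("list", P)
  score_list <- vector("list", P)
  means <- matrix(0, P, K)
  for (p in seq_len(P)) {
    jj <- (p - 1) * K + seq_len(K)
    Xp <- x[, jj, drop = FALSE]
    Mp <- mask[, jj, drop = FALSE]
    mu <- vapply(seq_len(K), function(j) {
      ok <- !Mp[, j]
      if (any(ok)) mean(Xp[ok, j]) else 0
    }, numeric(1))
    Xc <- sweep(Xp, 2, mu)
    Xc[Mp] <- 0  # masked entries sit at the element mean
    C <- crossprod(Xc) / (n - 1)
    eg <- eigen(C, symmetric = TRUE)
    keep <- which(eg$values > 1e-12 * max(eg$values[1], 0) & eg$values > 0)
    U <- .fix_signs(eg$vectors[, keep, drop = FALSE])
    means[p, ] <- mu
    elements[[p]] <- list(eigenfunctions = U, eigenvalues = eg$values[keep])
    score_list[[p]] <- Xc %*% U
  }
  S <- do.call(cbind, score_list)
  M <- ncol(S)

  # step 2: eigendecomposition of the stacked-score covariance
  mu_s <- colMeans(S)
  Sc <- sweep(S, 2, mu_s)
  Cs <- crossprod(Sc) / (n - 1)
  total_var <- sum(diag(Cs))
  if (total_var <= 1e-300) {
    warn("Zero-variance block: no components retained (k = 0).")
    eg2 <- list(values = numeric(0), vectors = matrix(0, M, 0))
    k <- 0L
    cum_var <- numeric(0)
  } else {
    eg2 <- eigen(Cs, symmetric = TRUE)
    pos <- eg2$values > 1e-12 * eg2$values[1]
    eg2$values <- eg2$values[pos]
    eg2$vectors <- .fix_signs(eg2$vectors[, pos, drop = FALSE])
    cum_var <- cumsum(eg2$values) / sum(eg2$values)
    k <- if (!is.null(fixed_k)) {
      as.integer(min(fixed_k, length(eg2$values)))
    } else {
      which(cum_var >= threshold - 1e-12)[1]
    }
  }
  scores_full <- Sc %*% eg2$vectors
  structure(list(
    means = means, elements = elements, score_means = mu_s,
    weights = eg2$vectors, eigenvalues = eg2$values, cum_var = cum_var,
    total_var = total_var, k = k, threshold = threshold,
    fixed_k = fixed_k, P = P, K = K, n = n,
    n_univariate = vapply(elements, function(e) ncol(e$eigenfunctions),
                          integer(1)),
    scores = scores_full[, seq_len(k), drop = FALSE],
    scores_full = scores_full
  ), class = "mfpca")
}

# deterministic sign convention: largest-|entry| of each column positive
.fix_signs <- function(V) {
  if (!ncol(V)) return(V)
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Project new bin-AUC blocks onto a fitted MFPCA basis
#'
#' Applies the deterministic linear map fitted by [mfpca()] (per-element
#' centring at the training means, projection on the univariate
#' eigenfunctions, then on the combination weights). Applied to the
#' training block it reproduces the stored training scores.
#'
#' @param object A fitted `mfpca` model.
#' @param newdata Matrix (or `spatial_features` tibble) with `P * K`
#'   columns.
#' @param mask Optional logical mask; masked entries are treated as lying
#'   at the training mean.
#' @param all_components Return all components instead of the retained `k`?
#' @param ... Unused.
#' @return An `n x k` score matrix.
#' @export
predict.mfpca <- function(object, newdata, mask = NULL,
                          all_components = FALSE, ...) {
  if (inherits(newdata, "spatial_features")) {
    cols <- .bin_columns(newdata)
    mask <- mask %||% .feature_mask(newdata)[, cols, drop = FALSE]
    newdata <- as.matrix(as_tibble(newdata)[cols])
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$P * object$K) {
    abort(sprintf("Block has %d columns; model expects %d.",
                  ncol(newdata), object$P * object$K))
  }
  if (is.null(mask)) mask <- matrix(FALSE, nrow(newdata), ncol(newdata))
  S <- .mfpca_univariate_scores(object, newdata, mask)
  Z <- sweep(S, 2, object$score_means) %*% object$weights
  if (all_components) Z else Z[, seq_len(object$k), drop = FALSE]
}

.mfpca_univariate_scores <- function(object, x, mask) {
  K <- object$K
  do.call(cbind, lapply(seq_len(object$P), function(p) {
    jj <- (p - 1) * K + seq_len(K)
    Xc <- sweep(x[, jj, drop = FALSE], 2, object$means[p, ])
    Mp <- mask[, jj, drop = FALSE]
    Xc[Mp] <- 0
    Xc %*% object$elements[[p]]$eigenfunctions
  }))
}

#' Reconstruct a bin-AUC block from MFPCA scores
#'
#' Inverts the two projection steps (both orthonormal), mapping retained
#' scores back to the `P * K` bin space. With all components retained the
#' reconstruction is exact to numerical precision.
#'
#' @param object A fitted `mfpca` model.
#' @param scores Score matrix (defaults to the training scores).
#' @return An `n x (P * K)` matrix.
#' @export
mfpca_reconstruct <- function(object, scores = NULL) {
  scores <- scores %||% object$scores
  m <- ncol(scores)
  W <- object$weights[, seq_len(m), drop = FALSE]
  S_hat <- sweep(scores %*% t(W), 2, object$score_means, "+")
  K <- object$K
  out <- matrix(0, nrow(scores), object$P * K)
  off <- 0L
  for (p in seq_len(object$P)) {
    kp <- object$n_univariate[p]
    U <- object$elements[[p]]$eigenfunctions
    Sp <- S_hat[, off + seq_len(kp), drop = FALSE]
    out[, (p - 1) * K + seq_len(K)] <-
      sweep(Sp %*% t(U), 2, object$means[p, ], "+")
    off <- off + kp
  }
  out
}

#' @export
print.mfpca <- function(x, ...) {
  cat(sprintf(
    "<mfpca> P = %d interactions x K = %d bins, n = %d images\n", x$P, x$K,
    x$n))
  cat(sprintf("  retained k = %d components (%.1f%% of variance, threshold %.0f%%)\n",
              x$k, 100 * (if (x$k > 0) x$cum_var[x$k] else 0),
              100 * x$threshold))
  invisible(x)
}

#' @describeIn mfpca_tidiers One row per multivariate component:
#'   eigenvalue, variance fraction, cumulative fraction, retained flag.
#' @method tidy mfpca
#' @export
tidy.mfpca <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         prop_var = x$eigenvalues / sum(x$eigenvalues),
         cum_var = x$cum_var,
         retained = seq_along(x$eigenvalues) <= x$k)
}

#' Tidiers for MFPCA fits
#'
#' @param x A fitted `mfpca` model.
#' @param ... Unused.
#' @name mfpca_tidiers
NULL

#' @describeIn mfpca_tidiers One-row model summary.
#' @method glance mfpca
#' @export
glance.mfpca <- function(x, ...) {
  tibble(n = x$n, P = x$P, K = x$K, k = x$k, threshold = x$threshold,
         var_explained = if (x$k > 0) x$cum_var[x$k] else 0,
         n_univariate = sum(x$n_univariate))
}

#' Serialize / restore an MFPCA model as JSON
#'
#' Stores every quantity needed to reproduce the fitted linear map exactly
#' (means, eigenfunctions, combination weights, eigenvalues, k, threshold),
#' so a model fitted at training time can be re-used verbatim at
#' prediction time.
#'
#' @param object A fitted `mfpca` model.
#' @param path JSON file path.
#' @return `path` invisibly; [read_mfpca()] returns the restored model.
#' @export
write_mfpca <- function(object, path) {
  payload <- list(
    means = object$means,
    elements = lapply(object$elements, function(e) {
      list(eigenfunctions = e$eigenfunctions, eigenvalues = e$eigenvalues)
    }),
    score_means = object$score_means,
    weights = object$weights,
    eigenvalues = object$eigenvalues,
    cum_var = object$cum_var, total_var = object$total_var,
    k = object$k, threshold = object$threshold,
    P = object$P, K = object$K, n = object$n,
    n_univariate = object$n_univariate
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mfpca
#' @export
read_mfpca <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  mat <- function(m) do.call(rbind, lapply(m, num))  # rows written row-major
  p <- list(
    means = mat(raw$means),
    elements = lapply(raw$elements, function(e) {
      list(eigenfunctions = mat(e$eigenfunctions),
           eigenvalues = num(e$eigenvalues))
    }),
    score_means = num(raw$score_means),
    weights = mat(raw$weights),
    eigenvalues = num(raw$eigenvalues),
    cum_var = num(raw$cum_var), total_var = as.numeric(raw$total_var),
    k = as.integer(raw$k), threshold = as.numeric(raw$threshold),
    P = as.integer(raw$P), K = as.integer(raw$K), n = as.integer(raw$n),
    n_univariate = as.integer(unlist(raw$n_univariate))
  )
  structure(p, class = "mfpca")
}
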
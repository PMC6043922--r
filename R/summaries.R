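#' Area under a G-curve
#'
#' Trapezoidal integral of the piecewise-linear G-curve over `[0, r_max]`.
#' Unnormalised, the result is an area in microns; with `normalize = TRUE`
#' it is divided by `r_max`, giving a value in `[0, 1]`. `r_max` values off
#' the evaluation grid are handled by linear interpolation at the interval
#' end points.
#'
#' @param curve A `g_curve` from [gcross()].
#' @param r_max Upper integration limit; defaults to the full curve range.
#'   Must not exceed `max(curve$r)`.
#' @param normalize Divide by the integration range?
#' @return A single number, or `NA_real_` for an undefined curve.
#' @examples
#' r <- seq(0, 20, length.out = 101)
#' cv <- structure(tibble::tibble(r = r, g = r / 20),
#'                 class = c("g_curve", class(tibble::tibble())),
#'                 defined = TRUE)
#' simple_auc(cv)  # 10
#' @export
simple_auc <- function(curve, r_max = NULL, normalize = FALSE) {
  r_max <- r_max %||% max(curve$r)
  if (r_max > max(curve$r) + 1e-9) {
    abort("`r_max` exceeds the evaluation grid of the curve.")
  }
  if (!isTRUE(attr(curve, "defined", exact = TRUE) %||% !anyNA(curve$g))) {
    return(NA_real_)
  }
  a <- .trapz_interval(curve$r, curve$g, 0, r_max)
  if (normalize) a / r_max else a
}

#' K-bin areas under a G-curve
#'
#' Splits `[0, r_max]` into `K` equal-width bins and integrates the curve
#' over each, preserving the shape information a single area discards. The
#' bin areas sum to [simple_auc()] over the same range (exact partition of
#' the piecewise-linear integral).
#'
#' @inheritParams simple_auc
#' @param K Number of equal-width bins.
#' @param normalize Divide each bin area by the bin width?
#' @return Numeric vector of length `K` (all `NA` for an undefined curve).
#' @examples
#' # a linear curve g = r/20 on [0, 20] has bin areas 2.5 and 7.5 for K = 2
#' @export
kbins_auc <- function(curve, K, r_max = NULL, normalize = FALSE) {
  stopifnot(K >= 1)
  r_max <- r_max %||% max(curve$r)
  if (r_max > max(curve$r) + 1e-9) {
    abort("`r_max` exceeds the evaluation grid of the curve.")
  }
  if (!isTRUE(attr(curve, "defined", exact = TRUE) %||% !anyNA(curve$g))) {
    return(rep(NA_real_, K))
  }
  edges <- seq(0, r_max, length.out = K + 1)
  a <- vapply(seq_len(K), function(b) {
    .trapz_interval(curve$r, curve$g, edges[b], edges[b + 1])
  }, numeric(1))
  if (normalize) a / (r_max / K) else a
}

# integral of the piecewise-linear interpolant of (r, g) over [a, b]
.trapz_interval <- function(r, g, a, b) {
  if (b <= a) return(0)
  inner <- r[r > a & r < b]
  xs <- c(a, inner, b)
  ys <- approx(r, g, xout = xs, rule = 2)$y
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Morisita-Horn colocalization index
#'
#' Quadrat-based overlap of two cell populations. The window is tiled by
#' square quadrats of side `quadrat_size` (partial quadrats at the right
#' and bottom edges included); with per-quadrat counts \eqn{x_q, y_q} and
#' totals \eqn{X, Y},
#' \deqn{MH = \frac{2 \sum_q x_q y_q}{(\sum_q x_q^2/X^2 + \sum_q y_q^2/Y^2)\, X Y}.}
#' The index lies in `[0, 1]`: 1 for proportionally identical quadrat
#' profiles, 0 when no quadrat holds both types. It is symmetric in the two
#' types and invariant to quadrat relabelling.
#'
#' @param cells Cell table of a single image.
#' @param type_a,type_b Phenotype (or any logical mark) column names.
#' @param window Observation window; defaults to the attached one.
#' @param quadrat_size Quadrat side length in microns.
#' @return A single number in `[0, 1]`, or `NA_real_` when either type is
#'   absent.
#' @export
morisita_horn <- function(cells, type_a, type_b, window = NULL,
                          quadrat_size = 100) {
  stopifnot(quadrat_size > 0)
  window <- .get_window(cells, window)
  if (!all(c(type_a, type_b) %in% names(cells))) {
    cells <- .ensure_phenotypes(cells)
  }
  nx <- max(1L, ceiling(window$width / quadrat_size))
  ny <- max(1L, ceiling(window$height / quadrat_size))
  qid <- function(sel) {
    ix <- pmin(floor(cells$x[sel] / quadrat_size), nx - 1L)
    iy <- pmin(floor(cells$y[sel] / quadrat_size), ny - 1L)
    tabulate(ix * ny + iy + 1L, nbins = nx * ny)
  }
  xq <- qid(cells[[type_a]])
  yq <- qid(cells[[type_b]])
  X <- sum(xq); Y <- sum(yq)
  if (X == 0 || Y == 0) return(NA_real_)
  2 * sum(xq * yq) / ((sum(xq^2) / X^2 + sum(yq^2) / Y^2) * X * Y)
}
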
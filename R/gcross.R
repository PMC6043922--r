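#' Cross-type nearest-neighbour distribution function (G-cross)
#'
#' Estimates, as a function of distance r, the probability that a cell of
#' the reference phenotype has at least one cell of the target phenotype
#' within distance r. Rising G-cross curves signal infiltration of the
#' target population into the neighbourhood of the reference population;
#' under complete spatial randomness of the targets with intensity lambda,
#' G(r) = 1 - exp(-lambda * pi * r^2).
#'
#' Nearest-neighbour distances of reference cells close to the image border
#' are censored by the boundary. Three estimators are provided:
#' \describe{
#'   \item{`none`}{the raw empirical CDF of per-reference nearest-target
#'     distances (negatively biased near the border);}
#'   \item{`border`}{the reduced-sample estimator, which at each r keeps
#'     only reference cells at least r from the boundary. It is not
#'     intrinsically monotone; empty risk sets are filled by carrying the
#'     last value forward and the curve is made non-decreasing by a
#'     cumulative maximum;}
#'   \item{`km`}{the Kaplan-Meier product-limit estimator treating the
#'     distance to the boundary as a right-censoring time (the default).}
#' }
#'
#' A cell carrying both phenotypes uses the distance to the nearest *other*
#' target cell; distinct cells at identical coordinates count at r = 0.
#'
#' @param cells Cell table of a single image. `ref` and `target` may be any
#'   logical columns; phenotype columns are derived from marker columns
#'   when absent.
#' @param ref,target Column names of the reference and target phenotypes.
#' @param window Observation window ([obs_window()]); defaults to the one
#'   attached to `cells`.
#' @param r_max Maximum distance (um) of the evaluation grid.
#' @param grid_points Number of equally spaced grid values on `[0, r_max]`.
#' @param correction Edge correction, one of `"km"`, `"border"`, `"none"`.
#' @return A `g_curve`: a tibble with columns `r` and `g`, and attributes
#'   `correction`, `n_reference`, `n_target`, `defined`, `ref`, `target`.
#'   When either phenotype is absent the curve is undefined: `g` is all
#'   `NA` and attribute `defined` is `FALSE` (no error is thrown).
#' @examples
#' cells <- data.frame(x = c(500, 510), y = c(500, 500),
#'                     ref = c(TRUE, FALSE), tgt = c(FALSE, TRUE))
#' g <- gcross(cells, "ref", "tgt", obs_window(1000, 1000),
#'             r_max = 20, correction = "none")
#' @export
gcross <- function(cells, ref, target, window = NULL, r_max = 32,
                   grid_points = 201,
                   correction = c("km", "border", "none")) {
  correction <- match.arg(correction)
  stopifnot(r_max > 0, grid_points >= 2)
  window <- .get_window(cells, window)
  if (!all(c(ref, target) %in% names(cells))) {
    cells <- .ensure_phenotypes(cells)
  }
  for (col in c(ref, target)) {
    if (!col %in% names(cells) || !is.logical(cells[[col]])) {
      abort(sprintf("`%s` is not a logical mark column of the cell table.", col))
    }
  }
  r_grid <- seq(0, r_max, length.out = grid_points)
  i_ref <- which(cells[[ref]])
  i_tgt <- which(cells[[target]])
  n_ref <- length(i_ref)
  n_tgt <- length(i_tgt)
  if (n_ref == 0L || n_tgt == 0L) {
    return(.new_g_curve(r_grid, rep(NA_real_, grid_points), correction,
                        n_ref, n_tgt, FALSE, ref, target, window))
  }

  d <- .nn_dist(cells$x[i_ref], cells$y[i_ref], i_ref,
                cells$x[i_tgt], cells$y[i_tgt], i_tgt)
  g <- switch(correction,
    none = vapply(r_grid, function(r) mean(d <= r), numeric(1)),
    border = {
      b <- .border_dist(cells$x[i_ref], cells$y[i_ref], window)
      num <- vapply(r_grid, function(r) sum(d <= r & b >= r), numeric(1))
      den <- vapply(r_grid, function(r) sum(b >= r), numeric(1))
      gb <- ifelse(den > 0, num / den, NA_real_)
      cummax(.locf(gb, first = 0))
    },
    km = {
      b <- .border_dist(cells$x[i_ref], cells$y[i_ref], window)
      .km_cdf(pmin(d, b), d <= b, r_grid)
    }
  )
  .new_g_curve(r_grid, pmin(pmax(g, 0), 1), correction, n_ref, n_tgt, TRUE,
               ref, target, window)
}

# nearest-target distance per reference cell, excluding the cell itself
# when the same cell row is both reference and target
.nn_dist <- function(xr, yr, idr, xt, yt, idt) {
  D <- sqrt(outer(xr, xt, "-")^2 + outer(yr, yt, "-")^2)
  self <- outer(idr, idt, "==")
  if (any(self)) D[self] <- Inf
  jmin <- max.col(-D, ties.method = "first")
  D[cbind(seq_along(xr), jmin)]
}

.border_dist <- function(x, y, window) {
  pmin(x, window$width - x, y, window$height - y)
}

# Kaplan-Meier product-limit CDF of right-censored nearest distances,
# evaluated on r_grid. time = min(distance, border), event = uncensored.
.km_cdf <- function(time, event, r_grid) {
  o <- order(time, !event)  # events precede censorings at tied times
  time <- time[o]
  event <- event[o]
  n <- length(time)
  at_risk <- n - seq_len(n) + 1L
  # aggregate tied times: product over distinct event times
  surv_steps <- ifelse(event, 1 - 1 / at_risk, 1)
  surv <- cumprod(surv_steps)
  # step function: S(r) = surv at largest time <= r (1 before first time)
  idx <- findInterval(r_grid, time)
  s <- c(1, surv)[idx + 1L]
  cummax(1 - s)
}

.locf <- function(v, first = 0) {
  if (is.na(v[1])) v[1] <- first
  for (i in seq_along(v)[-1]) if (is.na(v[i])) v[i] <- v[i - 1]
  v
}

.new_g_curve <- function(r, g, correction, n_ref, n_tgt, defined,
                         ref, target, window) {
  out <- tibble(r = r, g = g)
  class(out) <- c("g_curve", class(out))
  attr(out, "correction") <- correction
  attr(out, "n_reference") <- n_ref
  attr(out, "n_target") <- n_tgt
  attr(out, "defined") <- defined
  attr(out, "ref") <- ref
  attr(out, "target") <- target
  attr(out, "window") <- window
  out
}

#' @export
print.g_curve <- function(x, ...) {
  cat(sprintf(
    "<g_curve> %s -> %s, %s correction, %d reference / %d target cells%s\n",
    attr(x, "ref"), attr(x, "target"), attr(x, "correction"),
    attr(x, "n_reference"), attr(x, "n_target"),
    if (attr(x, "defined")) "" else " (undefined)"))
  NextMethod()
}

#' Export G-curves as a tidy table
#'
#' @param curves A `g_curve` or list of them.
#' @param image_id Optional image identifier(s) recycled across curves.
#' @return A tibble with columns `image_id`, `ref`, `target`, `correction`,
#'   `r`, `g`, suitable for CSV export and plotting.
#' @export
gcurve_table <- function(curves, image_id = NA_character_) {
  if (inherits(curves, "g_curve")) curves <- list(curves)
  image_id <- rep_len(image_id, length(curves))
  bind_rows(lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    tibble(image_id = image_id[i],
           ref = attr(cv, "ref"), target = attr(cv, "target"),
           correction = attr(cv, "correction"), r = cv$r, g = cv$g)
  }))
}
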
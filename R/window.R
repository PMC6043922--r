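#' Rectangular observation window of a multiplexed image
#'
#' Physical extent of one image field, in microns. The defaults are the
#' dimensions of a standard multispectral field: 2.1 mm x 1.6 mm scanned at
#' 1.57 um per pixel. Coordinates use the raster convention: origin at the
#' top-left corner, x rightward, y downward, continuous and 0-based; every
#' statistic in the package is invariant to this choice.
#'
#' @param width,height Window extent in microns. Must be positive.
#' @param resolution Microns per pixel, used to convert pixel-unit inputs.
#' @return An object of class `obs_window`: a list with elements `width`,
#'   `height`, `resolution` and derived `area` (um^2).
#' @examples
#' obs_window()
#' obs_window(1000, 1000)
#' @export
obs_window <- function(width = 2100, height = 1600, resolution = 1.57) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(resolution))
  if (width <= 0 || height <= 0 || resolution <= 0) {
    abort("`width`, `height` and `resolution` must all be positive.")
  }
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         resolution = as.numeric(resolution),
         area = as.numeric(width) * as.numeric(height)),
    class = "obs_window"
  )
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf("<obs_window> %g um x %g um (%.2f um/pixel)\n",
              x$width, x$height, x$resolution))
  invisible(x)
}

#' Convert between microns and pixels
#'
#' Distance thresholds are quoted in both unit systems in practice; the pixel
#' form is rounded to the nearest integer pixel (so 32 um -> 20 px and
#' 24 um -> 15 px at 1.57 um/pixel). Note that published pixel equivalences
#' are not always self-consistent at larger distances; these helpers always
#' use `round(r / resolution)`.
#'
#' @param r Distance(s) in microns (or pixels for [pixels_to_microns()]).
#' @param resolution Microns per pixel.
#' @return Numeric vector of converted distances.
#' @examples
#' microns_to_pixels(c(32, 24))  # 20, 15
#' @export
microns_to_pixels <- function(r, resolution = 1.57) {
  round(r / resolution)
}

#' @rdname microns_to_pixels
#' @export
pixels_to_microns <- function(r, resolution = 1.57) {
  r * resolution
}

# window attached to a cell table (falls back to the standard field)
.get_window <- function(cells, window = NULL) {
  w <- window %||% attr(cells, "window", exact = TRUE)
  if (is.null(w)) w <- obs_window()
  stopifnot(inherits(w, "obs_window"))
  w
}

.check_inside_window <- function(x, y, window, context = "cell table") {
  bad <- which(x < 0 | y < 0 | x > window$width | y > window$height)
  if (length(bad)) {
    abort(sprintf(
      "%s: %d cell(s) outside the %g x %g um observation window (rows %s).",
      context, length(bad), window$width, window$height,
      paste(head(bad, 10), collapse = ", ")))
  }
  invisible(TRUE)
}
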
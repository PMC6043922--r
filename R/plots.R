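#' Plot a G-cross curve
#'
#' @param object A `g_curve` from [gcross()].
#' @param ... Unused.
#' @return A ggplot: G(r) against distance r (um).
#' @method autoplot g_curve
#' @export
autoplot.g_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "distance r (µm)",
      y = "G(r)",
      title = sprintf("G-cross: %s → %s (%s correction)",
                      attr(object, "ref"), attr(object, "target"),
                      attr(object, "correction"))) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of an evaluation
#'
#' @param object A `spatial_eval` from [classify_images()].
#' @param ... Unused.
#' @return A ggplot of the out-of-fold ROC curve with the chance diagonal.
#' @method autoplot spatial_eval
#' @export
autoplot.spatial_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#d95f02") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("Task %s: AUC %.2f (%.0f%% CI %.2f-%.2f)",
                      object$task, object$auc, 100 * attr(object$ci, "level"),
                      object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}

#' Bar chart of interaction importance
#'
#' @param importance An importance tibble from [interaction_importance()]
#'   or `classify_images(..., importance = TRUE)$importance`.
#' @return A ggplot of mean decrease in classification accuracy per
#'   interaction.
#' @export
plot_importance <- function(importance) {
  d <- as_tibble(importance)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_decrease_accuracy,
                                  y = .data$label)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::labs(x = "mean decrease in classification accuracy (%)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Map the cells of one image
#'
#' Scatter of cell positions coloured by their most specific phenotype
#' (unlabelled cells in grey), with the window drawn to scale.
#'
#' @param cells Cell table of a single image.
#' @param window Observation window; defaults to the attached one.
#' @return A ggplot.
#' @export
plot_cells <- function(cells, window = NULL) {
  window <- .get_window(cells, window)
  cells <- .ensure_phenotypes(cells)
  lab <- rep("other", nrow(cells))
  for (p in phenotypes()) lab[cells[[p]]] <- p  # later = more specific
  d <- tibble(x = cells$x, y = cells$y,
              phenotype = factor(lab, levels = c(phenotypes(), "other")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$phenotype)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    # raster convention: y increases downward
    ggplot2::coord_fixed(xlim = c(0, window$width),
                         ylim = c(window$height, 0)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
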
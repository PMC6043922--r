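#' The canonical set of spatial interactions
#'
#' The twelve reference -> target phenotype pairs interrogated by the
#' platform: each of {Epithelial, EpithelialPDL1, Macrophage,
#' MacrophagePDL1} as reference against each of {Tcell, CytotoxicT,
#' AntigenExperiencedT} as target, in reference-major order (so the first
#' pair is all epithelial cells vs all T lymphocytes).
#'
#' @return A tibble with columns `ref`, `target` and `label` (P = 12 rows).
#' @examples
#' interaction_set()
#' @export
interaction_set <- function() {
  refs <- c("Epithelial", "EpithelialPDL1", "Macrophage", "MacrophagePDL1")
  targets <- c("Tcell", "CytotoxicT", "AntigenExperiencedT")
  out <- tidyr::expand_grid(ref = refs, target = targets)
  out$label <- paste(out$ref, out$target, sep = "_")
  out
}

#' Per-image spatial feature matrix
#'
#' Computes, for every image in a cell table, the selected feature blocks
#' over the P = 12 canonical interactions:
#' \describe{
#'   \item{`kbins`}{P x K bin areas of the G-cross curve over `[0, r_max]`
#'     (columns `bin_<ref>_<target>_<b>`, interaction-major, bin-minor);}
#'   \item{`simple_auc`}{P total areas (`auc_<ref>_<target>`);}
#'   \item{`counts`}{the 7 phenotype counts (`n_<phenotype>`);}
#'   \item{`morisita`}{P Morisita-Horn indices (`mh_<ref>_<target>`).}
#' }
#' An interaction whose reference or target phenotype is absent from an
#' image yields an undefined curve; its feature entries are set to 0 (no
#' infiltration observed at any r) and flagged in the missingness mask kept
#' as attribute `"mask"`, so downstream models can distinguish genuine
#' zeros from absent phenotypes.
#'
#' @param cells Phenotyped cell table covering one or more images.
#' @param window Observation window; defaults to the attached one.
#' @param r_max Maximum G-cross distance (um).
#' @param K Number of equal-width bins for the `kbins` block.
#' @param correction Edge correction passed to [gcross()].
#' @param grid_points Evaluation grid size passed to [gcross()].
#' @param quadrat_size Quadrat side (um) for the Morisita-Horn block.
#' @param metrics Character subset of
#'   `c("kbins", "simple_auc", "counts", "morisita")`.
#' @return A tibble, one row per image: `image_id`, `patient_id`,
#'   `region_grade`, then the feature columns; attributes `mask` (logical
#'   matrix over feature columns) and `config`.
#' @export
spatial_features <- function(cells, window = NULL, r_max = 32, K = 7,
                             correction = c("km", "border", "none"),
                             grid_points = 201, quadrat_size = 100,
                             metrics = c("kbins", "simple_auc", "counts",
                                         "morisita")) {
  correction <- match.arg(correction)
  valid <- c("kbins", "simple_auc", "counts", "morisita")
  bad <- setdiff(metrics, valid)
  if (length(bad)) {
    abort(sprintf("Unknown metric(s): %s. Valid metrics are: %s.",
                  paste(bad, collapse = ", "), paste(valid, collapse = ", ")))
  }
  window <- .get_window(cells, window)
  cells <- .ensure_phenotypes(cells)
  if (nrow(cells) == 0 || length(unique(cells$image_id)) == 0) {
    abort("Cell table contains no images.")
  }
  ints <- interaction_set()
  P <- nrow(ints)
  imgs <- image_split(cells)

  rows <- lapply(imgs, function(ci) {
    meta <- tibble(image_id = ci$image_id[1],
                   patient_id = ci$patient_id[1] %||% NA_character_,
                   region_grade = ci$region_grade[1])
    needs_g <- any(c("kbins", "simple_auc") %in% metrics)
    curves <- if (needs_g) {
      lapply(seq_len(P), function(p) {
        gcross(ci, ints$ref[p], ints$target[p], window = window,
               r_max = r_max, grid_points = grid_points,
               correction = correction)
      })
    }
    undef <- if (needs_g) {
      !vapply(curves, attr, logical(1), which = "defined")
    } else {
      counts <- phenotype_counts(ci)
      counts[ints$ref] == 0 | counts[ints$target] == 0
    }
    feats <- list(); mask <- list()
    if ("kbins" %in% metrics) {
      bins <- lapply(curves, kbins_auc, K = K, r_max = r_max)
      v <- unlist(bins)
      nm <- as.vector(t(outer(ints$label, seq_len(K),
                              function(l, b) paste0("bin_", l, "_", b))))
      feats$bins <- setNames(ifelse(is.na(v), 0, v), nm)
      mask$bins <- setNames(rep(undef, each = K), nm)
    }
    if ("simple_auc" %in% metrics) {
      v <- vapply(curves, simple_auc, numeric(1), r_max = r_max)
      nm <- paste0("auc_", ints$label)
      feats$auc <- setNames(ifelse(is.na(v), 0, v), nm)
      mask$auc <- setNames(undef, nm)
    }
    if ("counts" %in% metrics) {
      v <- phenotype_counts(ci)
      nm <- paste0("n_", phenotypes())
      feats$counts <- setNames(as.numeric(v), nm)
      mask$counts <- setNames(rep(FALSE, length(v)), nm)
    }
    if ("morisita" %in% metrics) {
      v <- vapply(seq_len(P), function(p) {
        morisita_horn(ci, ints$ref[p], ints$target[p], window = window,
                      quadrat_size = quadrat_size)
      }, numeric(1))
      nm <- paste0("mh_", ints$label)
      feats$mh <- setNames(ifelse(is.na(v), 0, v), nm)
      mask$mh <- setNames(is.na(v), nm)
    }
    list(row = bind_cols(meta, as_tibble(as.list(unlist(unname(feats))))),
         mask = unlist(unname(mask)))
  })

  out <- bind_rows(lapply(rows, `[[`, "row"))
  mask <- do.call(rbind, lapply(rows, `[[`, "mask"))
  rownames(mask) <- NULL
  attr(out, "mask") <- mask
  attr(out, "config") <- list(
    r_max = r_max, K = K, P = P, correction = correction,
    grid_points = grid_points, quadrat_size = quadrat_size,
    metrics = metrics, window = window[c("width", "height", "resolution")])
  class(out) <- c("spatial_features", class(out))
  out
}

# column index helpers for feature blocks
.bin_columns <- function(features) {
  grep("^bin_", names(features), value = TRUE)
}
.block_columns <- function(features, block) {
  prefix <- switch(block, kbins = "^bin_", mfpca = "^bin_",
                   simple_auc = "^auc_", counts = "^n_", morisita = "^mh_")
  grep(prefix, names(features), value = TRUE)
}
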
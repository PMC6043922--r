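#' Phenotype and marker vocabularies
#'
#' The package quantifies seven cell phenotypes defined from a six-marker
#' immunofluorescence panel: pan-cytokeratin AE1/AE3 (epithelium), PD-L1,
#' CD3 (T lymphocytes), CD8 (cytotoxic T cells), PD-1 (antigen-experienced
#' T cells) and CD68 (macrophages). Phenotypes are nested: a CD3+CD8+ cell
#' is both a `Tcell` and a `CytotoxicT`.
#'
#' @return Character vector of the seven phenotype labels
#'   (or six marker names).
#' @examples
#' phenotypes()
#' markers()
#' @export
phenotypes <- function() {
  c("Epithelial", "EpithelialPDL1", "Tcell", "AntigenExperiencedT",
    "CytotoxicT", "Macrophage", "MacrophagePDL1")
}

#' @rdname phenotypes
#' @export
markers <- function() {
  c("AE1AE3", "PDL1", "CD3", "CD8", "PD1", "CD68")
}

#' Assign cell phenotypes from marker positivity
#'
#' Applies the panel's gating rules to boolean marker flags:
#' * `Epithelial` = AE1/AE3+; `EpithelialPDL1` = AE1/AE3+ PD-L1+
#' * `Tcell` = CD3+; `AntigenExperiencedT` = CD3+ PD-1+;
#'   `CytotoxicT` = CD3+ CD8+
#' * `Macrophage` = CD68+; `MacrophagePDL1` = CD68+ PD-L1+
#'
#' A cell matching no rule gets no label; such cells stay in the pattern but
#' are excluded from every interaction and count. The nesting invariants
#' (e.g. `CytotoxicT` implies `Tcell`) hold by construction.
#'
#' @param x A data frame with logical (or 0/1) columns named as [markers()].
#' @return A tibble with one logical column per phenotype, one row per cell.
#' @examples
#' assign_phenotypes(data.frame(AE1AE3 = TRUE, PDL1 = TRUE, CD3 = FALSE,
#'                              CD8 = FALSE, PD1 = FALSE, CD68 = FALSE))
#' @export
assign_phenotypes <- function(x) {
  missing_keys <- setdiff(markers(), names(x))
  if (length(missing_keys)) {
    abort(sprintf("Marker column(s) missing from input: %s.",
                  paste(missing_keys, collapse = ", ")))
  }
  m <- lapply(markers(), function(k) {
    v <- x[[k]]
    if (is.numeric(v)) v <- v != 0
    if (!is.logical(v)) {
      abort(sprintf("Marker column `%s` must be logical or 0/1.", k))
    }
    if (anyNA(v)) abort(sprintf("Marker column `%s` contains NA.", k))
    v
  })
  names(m) <- markers()
  tibble(
    Epithelial          = m$AE1AE3,
    EpithelialPDL1      = m$AE1AE3 & m$PDL1,
    Tcell               = m$CD3,
    AntigenExperiencedT = m$CD3 & m$PD1,
    CytotoxicT          = m$CD3 & m$CD8,
    Macrophage          = m$CD68,
    MacrophagePDL1      = m$CD68 & m$PDL1
  )
}

#' Add phenotype columns to a cell table
#'
#' Convenience wrapper: binds the seven phenotype indicator columns of
#' [assign_phenotypes()] onto a per-cell table, replacing any existing
#' phenotype columns. Attributes (such as the observation window) are kept.
#'
#' @param cells Data frame of cells with marker columns.
#' @return The input tibble with seven additional logical phenotype columns.
#' @export
add_phenotypes <- function(cells) {
  ph <- assign_phenotypes(cells)
  keep <- setdiff(names(cells), phenotypes())
  out <- bind_cols(as_tibble(cells[keep]), ph)
  attributes(out)[setdiff(names(attributes(cells)), c("names", "row.names", "class"))] <-
    attributes(cells)[setdiff(names(attributes(cells)), c("names", "row.names", "class"))]
  out
}

#' Per-phenotype cell counts of one image
#'
#' Counts cells carrying each of the seven phenotype labels. Nested
#' phenotypes are counted in both parent and child: one CD3+CD8+ cell
#' contributes to `Tcell` and to `CytotoxicT`.
#'
#' @param cells Cell table of a single image; phenotype columns are added
#'   from the marker columns when absent.
#' @return Named integer vector of length 7, in [phenotypes()] order.
#' @examples
#' cells <- data.frame(x = 1, y = 1, AE1AE3 = FALSE, PDL1 = FALSE,
#'                     CD3 = TRUE, CD8 = TRUE, PD1 = FALSE, CD68 = FALSE)
#' phenotype_counts(cells)
#' @export
phenotype_counts <- function(cells) {
  cells <- .ensure_phenotypes(cells)
  vapply(phenotypes(), function(p) sum(cells[[p]]), integer(1))
}

.ensure_phenotypes <- function(cells) {
  if (all(phenotypes() %in% names(cells))) return(cells)
  add_phenotypes(cells)
}
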
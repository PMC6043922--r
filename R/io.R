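#' Schema description for a cell-by-cell report
#'
#' Cell-level exports from image-analysis software differ in column naming
#' and coordinate units. A schema maps the canonical column names used by
#' this package onto the columns of a particular file and declares the
#' coordinate units.
#'
#' @param units Either `"um"` (coordinates already in microns) or `"px"`
#'   (pixels; converted to microns with the window resolution).
#' @param delim Field delimiter of the file.
#' @param columns Named character vector mapping canonical names
#'   (`image_id`, `patient_id`, `region_grade`, `x`, `y` and the six marker
#'   names of [markers()]) to the column names found in the file. Only the
#'   names that differ need to be given.
#' @return A list of class `cell_schema`.
#' @export
cell_schema <- function(units = c("um", "px"), delim = ",", columns = character()) {
  units <- match.arg(units)
  canonical <- c("image_id", "patient_id", "region_grade", "x", "y", markers())
  map <- setNames(canonical, canonical)
  if (length(columns)) {
    unknown <- setdiff(names(columns), canonical)
    if (length(unknown)) {
      abort(sprintf("Unknown canonical column(s) in schema: %s.",
                    paste(unknown, collapse = ", ")))
    }
    map[names(columns)] <- unname(columns)
  }
  structure(list(units = units, delim = delim, columns = map),
            class = "cell_schema")
}

#' Read a cell-by-cell report into a phenotyped cell table
#'
#' Reads a delimited per-cell table (one row per cell: image and patient
#' identifiers, region grade, x/y coordinates and six boolean marker flags),
#' converts coordinates to microns, assigns the seven phenotypes and
#' validates that every cell lies inside the observation window.
#'
#' The observation window is resolved in this order: the `window` argument;
#' a JSON sidecar `<path>.json` with fields `width`, `height`, `resolution`;
#' the standard 2100 x 1600 um field. With `window = "bbox"` the window is
#' taken as the bounding box of the data (a warning is emitted, since
#' boundary corrections then treat the extreme cells as lying on the edge).
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [cell_schema()] describing the file layout.
#' @param window An [obs_window()], `NULL` (resolve as described) or
#'   `"bbox"`.
#' @return A tibble of cells (coordinates in um, logical marker and
#'   phenotype columns) with the window attached as attribute `"window"`.
#' @export
read_cell_table <- function(path, schema = cell_schema(), window = NULL) {
  stopifnot(inherits(schema, "cell_schema"))
  raw <- readr::read_delim(path, delim = schema$delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("Unparseable input in `%s`: first problem at line %d (%s).",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  map <- schema$columns
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols)) {
    abort(sprintf("Column(s) declared in schema but absent from `%s`: %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  cells <- tibble(
    image_id = as.character(raw[[map[["image_id"]]]]),
    patient_id = as.character(raw[[map[["patient_id"]]]]),
    region_grade = .parse_grade(raw[[map[["region_grade"]]]]),
    x = as.numeric(raw[[map[["x"]]]]),
    y = as.numeric(raw[[map[["y"]]]])
  )
  for (mk in markers()) cells[[mk]] <- .parse_marker(raw[[map[[mk]]]], mk)
  if (anyNA(cells$x) || anyNA(cells$y)) {
    abort(sprintf("Non-numeric coordinates in `%s` (first at line %d).",
                  path, which(is.na(cells$x) | is.na(cells$y))[1] + 1L))
  }

  if (identical(window, "bbox")) {
    warn("Using the data bounding box as observation window.")
    window <- obs_window(max(cells$x), max(cells$y))
  } else if (is.null(window)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      window <- obs_window(meta$width, meta$height,
                           meta$resolution %||% 1.57)
    } else {
      window <- obs_window()
    }
  }
  if (schema$units == "px") {
    cells$x <- cells$x * window$resolution
    cells$y <- cells$y * window$resolution
  }
  .check_inside_window(cells$x, cells$y, window, context = path)
  cells <- add_phenotypes(cells)
  attr(cells, "window") <- window
  cells
}

.parse_grade <- function(v) {
  g <- tolower(as.character(v))
  bad <- !g %in% c("low", "high")
  if (any(bad)) {
    abort(sprintf("`region_grade` must be low/high (first bad value: %s).",
                  g[bad][1]))
  }
  factor(g, levels = c("low", "high"))
}

.parse_marker <- function(v, name) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1))) {
      abort(sprintf("Marker column `%s` must contain 0/1.", name))
    }
    return(v == 1)
  }
  s <- tolower(trimws(as.character(v)))
  if (all(s %in% c("pos", "neg"))) return(s == "pos")
  if (all(s %in% c("0", "1"))) return(s == "1")
  if (all(s %in% c("true", "false"))) return(s == "true")
  abort(sprintf("Marker column `%s` has unrecognised encoding.", name))
}

#' Write a cell table in the dialect read by [read_cell_table()]
#'
#' Writes the cells as CSV (coordinates in microns) plus a JSON sidecar
#' `<path>.json` carrying the window metadata, so that reading the pair
#' back reproduces the same pattern.
#'
#' @param cells Phenotyped cell table (see [read_cell_table()]).
#' @param path Output CSV path.
#' @param window Observation window; defaults to the one attached to
#'   `cells`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, window = NULL) {
  window <- .get_window(cells, window)
  out <- as_tibble(cells)[c("image_id", "patient_id", "region_grade",
                            "x", "y", markers())]
  out[markers()] <- lapply(out[markers()], as.integer)
  readr::write_csv(out, path, progress = FALSE)
  jsonlite::write_json(
    list(width = window$width, height = window$height,
         resolution = window$resolution, n_cells = nrow(out)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a per-image feature table
#'
#' One row per image, metadata columns first, then the numeric feature
#' columns in a stable order. Entries flagged in the missingness mask
#' (features of an interaction whose reference or target phenotype was
#' absent from the image) are serialised as the sentinel `NA`, which is
#' distinguishable from a genuine 0; on reading they are restored as value
#' 0 with the mask set. Values round-trip exactly (shortest round-trip
#' decimal representation).
#'
#' @param features A feature tibble from [spatial_features()] (or a list of
#'   such tibbles with identical columns, which are stacked; heterogeneous
#'   column sets are an error).
#' @param path Output CSV path. A JSON sidecar `<path>.json` stores the
#'   window and summary configuration.
#' @return `path` invisibly, for the writer; the feature tibble (with
#'   attributes `mask` and `config` restored) for the reader.
#' @export
write_feature_table <- function(features, path) {
  if (is.list(features) && !is.data.frame(features)) {
    sets <- lapply(features, names)
    if (length(unique(vapply(sets, paste, "", collapse = "\r"))) > 1) {
      abort("Heterogeneous column sets: all feature tibbles must have identical columns.")
    }
    mask <- do.call(rbind, lapply(features, function(f) .feature_mask(f)))
    config <- attr(features[[1]], "config", exact = TRUE)
    features2 <- bind_rows(lapply(features, as_tibble))
    attr(features2, "mask") <- mask
    attr(features2, "config") <- config
    features <- features2
  }
  mask <- .feature_mask(features)
  meta_cols <- intersect(c("image_id", "patient_id", "region_grade"),
                         names(features))
  feat_cols <- setdiff(names(features), meta_cols)
  out <- as_tibble(features)[c(meta_cols, feat_cols)]
  for (j in feat_cols) {
    out[[j]][mask[, j]] <- NA_real_
  }
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  config <- attr(features, "config", exact = TRUE)
  if (!is.null(config)) {
    jsonlite::write_json(config, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs)) {
    abort(sprintf("Unparseable feature table `%s` (line %d).",
                  path, probs$row[1] + 1L))
  }
  meta_cols <- intersect(c("image_id", "patient_id", "region_grade"),
                         names(x))
  feat_cols <- setdiff(names(x), meta_cols)
  if ("region_grade" %in% meta_cols) {
    x$region_grade <- .parse_grade(x$region_grade)
  }
  mask <- matrix(FALSE, nrow(x), length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (j in feat_cols) {
    mask[, j] <- is.na(x[[j]])
    x[[j]][mask[, j]] <- 0
  }
  attr(x, "mask") <- mask
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(x, "config") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  x
}

# mask aligned to the feature columns; all-FALSE when absent
.feature_mask <- function(features) {
  meta_cols <- intersect(c("image_id", "patient_id", "region_grade"),
                         names(features))
  feat_cols <- setdiff(names(features), meta_cols)
  mask <- attr(features, "mask", exact = TRUE)
  if (!is.null(mask) && nrow(mask) != nrow(features)) mask <- NULL
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(features), length(feat_cols),
                   dimnames = list(NULL, feat_cols))
  }
  if (!all(feat_cols %in% colnames(mask))) {
    full <- matrix(FALSE, nrow(features), length(feat_cols),
                   dimnames = list(NULL, feat_cols))
    shared <- intersect(colnames(mask), feat_cols)
    full[, shared] <- mask[, shared]
    mask <- full
  }
  mask[, feat_cols, drop = FALSE]
}

#' Split a multi-image cell table into per-image patterns
#'
#' @param cells A phenotyped cell table covering one or more images.
#' @return A named list of single-image cell tibbles, each carrying the
#'   window attribute.
#' @export
image_split <- function(cells) {
  window <- .get_window(cells)
  ids <- unique(cells$image_id)
  out <- lapply(ids, function(id) {
    ci <- as_tibble(cells)[cells$image_id == id, , drop = FALSE]
    attr(ci, "window") <- window
    ci
  })
  setNames(out, ids)
}
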
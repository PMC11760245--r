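# Reading and writing cell tables, landmarks, transforms and match tables.
# Keeps the QuPath-export dialect quirks away from the math core.

#' Construct a cell table
#'
#' A cell table holds one modality's segmentation output: one row per cell
#' with its centroid (micrometers) and any per-cell features (area,
#' perimeter, solidity, mean stain intensity, ...). It is a plain data frame
#' with columns `cell_id`, `x`, `y` followed by feature columns, plus a
#' `modality` attribute.
#'
#' @param xy n x 2 centroid matrix in micrometers.
#' @param features Optional data frame / named list of numeric per-cell
#'   feature columns.
#' @param cell_id Optional character vector of unique ids; autogenerated when
#'   missing.
#' @param modality Free-text modality tag (e.g. `"HE"`, `"MxIF"`).
#' @return A data frame of class `cell_table`.
#' @export
cell_table <- function(xy, features = NULL, cell_id = NULL, modality = "") {
  p <- as_xy(xy)
  n <- nrow(p)
  if (!all(is.finite(p))) stop("centroids must be finite", call. = FALSE)
  if (is.null(cell_id)) cell_id <- sprintf("cell_%05d", seq_len(n))
  cell_id <- as.character(cell_id)
  if (length(cell_id) != n) stop("`cell_id` length does not match point count", call. = FALSE)
  if (anyDuplicated(cell_id)) stop("cell ids must be unique", call. = FALSE)
  out <- data.frame(cell_id = cell_id, x = p[, 1], y = p[, 2], stringsAsFactors = FALSE)
  if (!is.null(features)) {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    if (nrow(features) != n) stop("feature rows do not match point count", call. = FALSE)
    bad <- names(features)[!vapply(features, is.numeric, logical(1))]
    if (length(bad)) {
      stop("feature columns must be numeric: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    out <- cbind(out, features)
  }
  rownames(out) <- NULL
  attr(out, "modality") <- modality
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Feature column names of a cell table
#' @param cells A `cell_table`.
#' @export
cell_features <- function(cells) {
  setdiff(names(cells), c("cell_id", "x", "y"))
}

# Sniff the delimiter of a delimited text file from its first data line.
detect_delim <- function(path) {
  lines <- readLines(path, n = 25L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("empty input file: ", path, call. = FALSE)
  first <- lines[[1]]
  if (grepl("\t", first, fixed = TRUE)) "\t" else if (grepl(",", first, fixed = TRUE)) "," else ""
}

#' Read a per-cell measurement table
#'
#' Ingests a delimited text export of cell segmentation results (one row per
#' cell). Two column dialects are recognized: `"qupath"` (measurement-export
#' style, centroid columns `"Centroid X px"` / `"Centroid Y px"`) and
#' `"plain"` (`x` / `y`); `"auto"` picks whichever is present. Centroids are
#' converted to micrometers on ingestion by multiplying with `pixel_size`;
#' all other numeric columns are carried through untouched as features. Rows
#' with non-finite coordinates are dropped with a warning.
#'
#' @param path File path (TSV or CSV; delimiter auto-detected).
#' @param dialect `"auto"`, `"plain"` or `"qupath"`.
#' @param pixel_size Micrometers per pixel of the source image; use 1 when
#'   the table is already in micrometers.
#' @param modality Modality tag stored on the returned table.
#' @return A `cell_table` in micrometers.
#' @export
read_cell_table <- function(path, dialect = c("auto", "plain", "qupath"),
                            pixel_size = 1, modality = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    comment.char = "#", stringsAsFactors = FALSE, quote = "\""
  )
  if (nrow(raw) == 0L) stop("empty cell table: ", path, call. = FALSE)
  dialects <- list(
    qupath = c("Centroid X px", "Centroid Y px"),
    plain = c("x", "y")
  )
  pick <- switch(dialect,
    qupath = "qupath",
    plain = "plain",
    auto = {
      hit <- names(dialects)[vapply(dialects, function(cols) all(cols %in% names(raw)), logical(1))]
      if (!length(hit)) {
        stop("no recognized centroid columns (expected `x`/`y` or QuPath `Centroid X px`/`Centroid Y px`)",
          call. = FALSE
        )
      }
      hit[[1]]
    }
  )
  cols <- dialects[[pick]]
  missing <- setdiff(cols, names(raw))
  if (length(missing)) {
    stop("missing coordinate column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  xy_px <- cbind(as.numeric(raw[[cols[1]]]), as.numeric(raw[[cols[2]]]))
  ok <- is.finite(xy_px[, 1]) & is.finite(xy_px[, 2])
  if (!all(ok)) {
    warning(sprintf("dropped %d row(s) with non-finite coordinates", sum(!ok)), call. = FALSE)
    raw <- raw[ok, , drop = FALSE]
    xy_px <- xy_px[ok, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no rows with finite coordinates in ", path, call. = FALSE)
  id_col <- intersect(c("cell_id", "Object ID"), names(raw))
  ids <- if (length(id_col)) as.character(raw[[id_col[1]]]) else NULL
  feat_cols <- setdiff(names(raw), c(cols, id_col, "cell_id"))
  feat_cols <- feat_cols[vapply(raw[feat_cols], is.numeric, logical(1))]
  cell_table(
    pixels_to_microns(xy_px, pixel_size),
    features = if (length(feat_cols)) raw[feat_cols] else NULL,
    cell_id = ids,
    modality = modality
  )
}

#' Write a cell table to TSV
#'
#' Coordinates are written in micrometers with 4 decimals (0.1 nm, far below
#' biological noise); features at full precision.
#'
#' @param cells A `cell_table`.
#' @param path Output path.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(inherits(cells, "cell_table"))
  out <- as.data.frame(cells)
  out$x <- round(out$x, 4)
  out$y <- round(out$y, 4)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write landmark pair tables
#'
#' Landmark files are TSV with columns `source_x`, `source_y`, `target_x`,
#' `target_y`, one row per annotated pair, and a leading comment line
#' declaring the units (`# units: um` or `# units: px`). Pixel-unit files
#' require the per-modality pixel sizes for conversion.
#'
#' @param path File path.
#' @param source_pixel_size,target_pixel_size Micrometers per pixel, only
#'   needed when the file declares pixel units.
#' @return A `landmark_pairs` object in micrometers.
#' @export
read_landmarks <- function(path, source_pixel_size = NULL, target_pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 5L, warn = FALSE)
  units <- "um"
  unit_line <- grep("^#\\s*units:", header, value = TRUE)
  if (length(unit_line)) {
    units <- trimws(sub("^#\\s*units:\\s*", "", unit_line[[1]]))
  }
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE
  )
  need <- c("source_x", "source_y", "target_x", "target_y")
  if (!all(need %in% names(tab))) {
    stop("landmark file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  s <- cbind(tab$source_x, tab$source_y)
  t <- cbind(tab$target_x, tab$target_y)
  if (identical(units, "px")) {
    if (is.null(source_pixel_size) || is.null(target_pixel_size)) {
      stop("landmark file is in pixels; supply source_pixel_size and target_pixel_size",
        call. = FALSE
      )
    }
    s <- pixels_to_microns(s, source_pixel_size)
    t <- pixels_to_microns(t, target_pixel_size)
  }
  landmark_pairs(s, t)
}

#' @rdname read_landmarks
#' @param landmarks A `landmark_pairs` object (micrometers).
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_pairs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: um", con)
  tab <- data.frame(
    source_x = landmarks$source[, 1], source_y = landmarks$source[, 2],
    target_x = landmarks$target[, 1], target_y = landmarks$target[, 2]
  )
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a similarity transform as JSON
#'
#' The JSON object stores `theta_rad`, `scale`, `dx_um`, `dy_um` and the
#' 3x3 matrix (row-major) at full double precision, so a write/read
#' round-trip is bit-exact.
#'
#' @param tf A `rigid_transform`.
#' @param path File path.
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid_transform"))
  M <- transform_matrix(tf)
  obj <- list(
    theta_rad = tf$theta,
    scale = tf$scale,
    dx_um = tf$dx,
    dy_um = tf$dy,
    matrix = as.numeric(t(M))
  )
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("theta_rad", "scale", "dx_um", "dy_um")
  if (!all(need %in% names(obj))) {
    stop("transform JSON must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  rigid_transform(
    as.numeric(obj$theta_rad), as.numeric(obj$scale),
    as.numeric(obj$dx_um), as.numeric(obj$dy_um)
  )
}

#' Write / read a match table
#'
#' Match tables record putative cell-to-cell correspondences as TSV with
#' columns `source_id`, `target_id`, `affinity` and `kept_by_lpm`.
#'
#' @param matches A `match_set` (see [match_cells()]) or a data frame with
#'   the four columns above.
#' @param path File path.
#' @param source,target Optional cell tables for referential-integrity
#'   checking of the stored ids.
#' @export
write_match_table <- function(matches, path, source = NULL, target = NULL) {
  tab <- as.data.frame(matches)
  need <- c("source_id", "target_id", "affinity", "kept_by_lpm")
  if (!all(need %in% names(tab))) {
    stop("match table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is.null(source) && !all(tab$source_id %in% source$cell_id)) {
    stop("match table references source ids absent from the source table", call. = FALSE)
  }
  if (!is.null(target) && !all(tab$target_id %in% target$cell_id)) {
    stop("match table references target ids absent from the target table", call. = FALSE)
  }
  utils::write.table(tab[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_match_table
#' @export
read_match_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c(
      source_id = "character", target_id = "character",
      affinity = "numeric", kept_by_lpm = "logical"
    )
  )
  class(tab) <- c("match_set", "data.frame")
  tab
}
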
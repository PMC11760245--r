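# Post-alignment cross-modal concordance statistics: nearest-cell pairing
# with N = 0 / N = 1 / N > 1 triage, per-feature Pearson correlation,
# regional density grids and regional cell-composition similarity.

#' Nearest-cell pairing between aligned modalities
#'
#' Links each source cell (already mapped into target space) to its nearest
#' target cell within `radius`. Target cells claimed by exactly one source
#' give one-to-one pairs (`N=1`); targets claimed by several sources mark
#' under-segmentation-style conflicts (`N>1`); sources with no target within
#' the radius are unmatched (`N=0`). Shared feature columns are carried into
#' the result as `source_<f>` / `target_<f>` for correlation analysis.
#'
#' @param source_aligned A `cell_table` whose centroids are already in
#'   target space (apply the alignment transform first).
#' @param target A `cell_table`.
#' @param radius Pairing radius in micrometers (default 10, about one cell
#'   diameter).
#' @return A data frame of class `paired_features`: `source_id`,
#'   `target_id` (`NA` for `N=0`), `distance` (um), `n_class` plus paired
#'   feature columns.
#' @export
nearest_pairing <- function(source_aligned, target, radius = 10) {
  stopifnot(inherits(source_aligned, "cell_table"), inherits(target, "cell_table"))
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  sxy <- as_xy(source_aligned)
  txy <- as_xy(target)
  n <- nrow(sxy)
  # chunked nearest-neighbor search keeps memory bounded for large cores
  nn_idx <- integer(n)
  nn_d <- numeric(n)
  step <- max(1L, floor(2e6 / max(1L, nrow(txy))))
  for (start in seq(1L, n, by = step)) {
    rows <- start:min(start + step - 1L, n)
    d2 <- pairwise_sq_dist(sxy[rows, , drop = FALSE], txy)
    j <- max.col(-d2, ties.method = "first")
    nn_idx[rows] <- j
    nn_d[rows] <- sqrt(d2[cbind(seq_along(rows), j)])
  }
  within <- nn_d <= radius
  claimed <- table(nn_idx[within])
  multi <- as.integer(names(claimed)[claimed > 1L])
  n_class <- ifelse(!within, "N=0", ifelse(nn_idx %in% multi, "N>1", "N=1"))
  out <- data.frame(
    source_id = source_aligned$cell_id,
    target_id = ifelse(within, target$cell_id[nn_idx], NA_character_),
    distance = ifelse(within, nn_d, NA_real_),
    n_class = n_class,
    stringsAsFactors = FALSE
  )
  shared <- intersect(cell_features(source_aligned), cell_features(target))
  for (f in shared) {
    out[[paste0("source_", f)]] <- source_aligned[[f]]
    out[[paste0("target_", f)]] <- ifelse(within, target[[f]][nn_idx], NA_real_)
  }
  class(out) <- c("paired_features", "data.frame")
  out
}

#' Cross-modal Pearson correlation of a paired feature
#'
#' Product-moment correlation of a feature between the two modalities,
#' restricted to one-to-one (`N=1`) pairs -- the only pairs where the same
#' physical cell plausibly underlies both measurements.
#'
#' @param paired A `paired_features` from [nearest_pairing()].
#' @param feature Feature name (e.g. `"area"`).
#' @return A list with `r`, `p_value` (two-sided) and `n` (pairs used).
#' @export
feature_correlation <- function(paired, feature) {
  sc <- paste0("source_", feature)
  tc <- paste0("target_", feature)
  if (!all(c(sc, tc) %in% names(paired))) {
    stop("feature `", feature, "` is not paired in both modalities", call. = FALSE)
  }
  ok <- paired$n_class == "N=1" & is.finite(paired[[sc]]) & is.finite(paired[[tc]])
  x <- paired[[sc]][ok]
  y <- paired[[tc]][ok]
  if (length(x) < 3L) stop("need at least 3 one-to-one pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance on one side", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Regional cell-density grid
#'
#' Counts cells over an axis-aligned grid of square bins of side
#' `grid_size` covering `bbox` (default: the table's bounding box). The grid
#' total always equals the cell count.
#'
#' @param cells A `cell_table` or coordinate matrix.
#' @param grid_size Bin side length (um).
#' @param bbox Optional bounding box `c(xmin, xmax, ymin, ymax)`; pass the
#'   joint box when comparing two modalities on the same grid.
#' @return An integer matrix (rows = y bins, columns = x bins) with
#'   attributes `x_breaks`, `y_breaks`.
#' @export
regional_density <- function(cells, grid_size = 100, bbox = NULL) {
  if (grid_size <= 0) stop("`grid_size` must be > 0", call. = FALSE)
  xy <- as_xy(cells)
  if (is.null(bbox)) {
    bbox <- if (nrow(xy)) c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2])) else c(0, grid_size, 0, grid_size)
  }
  nx <- max(1L, ceiling((bbox[2] - bbox[1]) / grid_size))
  ny <- max(1L, ceiling((bbox[4] - bbox[3]) / grid_size))
  grid <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(xy)) {
    ix <- pmin(pmax(floor((xy[, 1] - bbox[1]) / grid_size) + 1L, 1L), nx)
    iy <- pmin(pmax(floor((xy[, 2] - bbox[3]) / grid_size) + 1L, 1L), ny)
    tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
    grid <- matrix(as.integer(tab), nrow = ny, ncol = nx)
  }
  attr(grid, "x_breaks") <- bbox[1] + grid_size * 0:nx
  attr(grid, "y_breaks") <- bbox[3] + grid_size * 0:ny
  grid
}

#' Regional cell-composition similarity map
#'
#' Compares per-region tumor proportions between the two aligned modalities:
#' for each grid bin, similarity = `1 - |p_source - p_target|` where `p` is
#' the proportion of label-positive (tumor) cells. Bins with fewer than
#' `min_cells` cells on either side are masked (`NA`). Labels come from an
#' upstream classifier and must be supplied as a binary (0/1) feature
#' column.
#'
#' @param source,target `cell_table`s in a common space.
#' @param label Name of the binary label column present in both tables.
#' @param grid_size Bin side length (um).
#' @param min_cells Minimum per-side cell count for an unmasked bin.
#' @param bbox Optional shared bounding box (default: joint box).
#' @return A numeric matrix of similarities in `[0, 1]` with `NA` in masked
#'   regions; same layout as [regional_density()].
#' @export
composition_similarity <- function(source, target, label = "tumor",
                                   grid_size = 100, min_cells = 10, bbox = NULL) {
  for (tab in list(source, target)) {
    if (!label %in% names(tab)) {
      stop("label column `", label, "` missing from a cell table", call. = FALSE)
    }
  }
  sxy <- as_xy(source)
  txy <- as_xy(target)
  if (is.null(bbox)) {
    allx <- c(sxy[, 1], txy[, 1])
    ally <- c(sxy[, 2], txy[, 2])
    bbox <- c(min(allx), max(allx), min(ally), max(ally))
  }
  count_s <- regional_density(sxy, grid_size, bbox)
  count_t <- regional_density(txy, grid_size, bbox)
  pos_s <- regional_density(sxy[source[[label]] > 0, , drop = FALSE], grid_size, bbox)
  pos_t <- regional_density(txy[target[[label]] > 0, , drop = FALSE], grid_size, bbox)
  p_s <- ifelse(count_s > 0, pos_s / count_s, NA_real_)
  p_t <- ifelse(count_t > 0, pos_t / count_t, NA_real_)
  sim <- 1 - abs(p_s - p_t)
  sim[count_s < min_cells | count_t < min_cells] <- NA_real_
  attr(sim, "x_breaks") <- attr(count_s, "x_breaks")
  attr(sim, "y_breaks") <- attr(count_s, "y_breaks")
  sim
}
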
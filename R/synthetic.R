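# Synthetic TMA-core generator: virtual cell-centroid pairs with known
# ground truth, used by the test suite and the acceptance checks.
#
# The generator emulates what the registration pipeline actually consumes --
# segmentation centroids plus per-cell morphology -- not images. Base
# centroids fill a disc-shaped core with density hotspots; the target side
# is the base cloud pushed through a known similarity transform; both sides
# are then independently perturbed with centroid jitter, cell dropout and
# over-/under-segmentation (splits and merges), the failure modes seen when
# different segmentation models run on different modalities.

#' Synthetic core configuration
#'
#' Defaults model one tissue-microarray core: radius 400 um (a core ~850 um
#' across), 1,000 cells, half of them in Gaussian density hotspots.
#'
#' @param n_cells Number of base cells (>= 10).
#' @param core_radius Core radius in micrometers.
#' @param n_clusters Number of density hotspots.
#' @param cluster_sd Hotspot Gaussian spread (um).
#' @param cluster_fraction Fraction of cells in hotspots (the rest are
#'   uniform over the disc).
#' @param true_transform The ground-truth `rigid_transform` mapping the
#'   source frame to the target frame.
#' @param jitter_sd Per-coordinate centroid jitter (um), applied
#'   independently per side.
#' @param dropout_rate Per-side probability that a cell is missing
#'   (washed-off cells, missed detections).
#' @param split_rate Probability that a cell is over-segmented into two
#'   children offset +/- 2 um along a random axis.
#' @param merge_rate Probability that a cell is under-segmented: fused with
#'   its nearest neighbor into one cell at their midpoint.
#' @param feature_noise_sd Log-scale sd of per-side multiplicative noise on
#'   morphology/intensity features.
#' @param feature_decorrelate If `TRUE` the target side redraws its features
#'   from the population instead of perturbing the shared per-cell values --
#'   emulating a serial section, where the imaged cells are physically
#'   different.
#' @param n_landmarks Number of landmark pairs to select (mutually distant
#'   cells surviving on both sides).
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 1000L, core_radius = 400, n_clusters = 5L,
                             cluster_sd = 40, cluster_fraction = 0.5,
                             true_transform = rigid_transform(deg2rad(5), 1, 20, -10),
                             jitter_sd = 0, dropout_rate = 0, split_rate = 0,
                             merge_rate = 0, feature_noise_sd = 0,
                             feature_decorrelate = FALSE,
                             n_landmarks = 8L, seed = 1L) {
  if (n_cells < 10L) stop("`n_cells` must be >= 10", call. = FALSE)
  rates <- c(dropout_rate, split_rate, merge_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("dropout/split/merge rates must lie in [0, 1)", call. = FALSE)
  }
  if (!inherits(true_transform, "rigid_transform")) {
    stop("`true_transform` must be a rigid_transform", call. = FALSE)
  }
  structure(
    list(
      n_cells = as.integer(n_cells), core_radius = core_radius,
      n_clusters = as.integer(n_clusters), cluster_sd = cluster_sd,
      cluster_fraction = cluster_fraction, true_transform = true_transform,
      jitter_sd = jitter_sd, dropout_rate = dropout_rate,
      split_rate = split_rate, merge_rate = merge_rate,
      feature_noise_sd = feature_noise_sd,
      feature_decorrelate = isTRUE(feature_decorrelate),
      n_landmarks = as.integer(n_landmarks), seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Preset synthetic study conditions
#'
#' Named configurations used throughout the tests:
#' \describe{
#'   \item{`clean`}{no noise of any kind -- the transform-recovery oracle.}
#'   \item{`restained`}{same physical section imaged twice: low dropout
#'     (5\%), 0.5 um jitter, rare splits/merges, mild feature noise,
#'     features shared across sides.}
#'   \item{`serial`}{adjacent 5-um section: heavy dropout (30\%), 2 um
#'     jitter, decorrelated features -- different physical cells.}
#'   \item{`degraded`}{stress condition for transform recovery: 20\%
#'     dropout per side, 1 um jitter, 2\% splits and merges.}
#' }
#'
#' @param profile One of `"clean"`, `"restained"`, `"serial"`, `"degraded"`.
#' @param ... Overrides passed on to [synthetic_config()].
#' @export
synthetic_profile <- function(profile = c("clean", "restained", "serial", "degraded"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    clean = list(),
    restained = list(
      jitter_sd = 0.5, dropout_rate = 0.05, split_rate = 0.01,
      merge_rate = 0.01, feature_noise_sd = 0.05
    ),
    serial = list(
      jitter_sd = 2, dropout_rate = 0.3, split_rate = 0.02,
      merge_rate = 0.02, feature_noise_sd = 0.3, feature_decorrelate = TRUE
    ),
    degraded = list(
      jitter_sd = 1, dropout_rate = 0.2, split_rate = 0.02,
      merge_rate = 0.02, feature_noise_sd = 0.05
    )
  )
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

# Per-cell morphology drawn once and shared by both sides (before
# perturbation): lognormal nuclear area, perimeter tied to area with a
# roughness factor, beta-distributed solidity, lognormal stain intensity.
draw_base_features <- function(n) {
  area <- stats::rlnorm(n, log(35), 0.25)
  roughness <- stats::rlnorm(n, log(1.15), 0.06)
  data.frame(
    area = area,
    perimeter = 2 * sqrt(pi * area) * roughness,
    solidity = stats::rbeta(n, 36, 4),
    intensity = stats::rlnorm(n, log(100), 0.4)
  )
}

perturb_features <- function(feats, noise_sd, decorrelate) {
  n <- nrow(feats)
  if (decorrelate) {
    return(draw_base_features(n))
  }
  if (noise_sd > 0) {
    for (f in c("area", "perimeter", "intensity")) {
      feats[[f]] <- feats[[f]] * stats::rlnorm(n, 0, noise_sd)
    }
    feats$solidity <- pmin(pmax(feats$solidity + stats::rnorm(n, 0, noise_sd / 5), 0.01), 1)
  }
  feats
}

# Apply one side's perturbations. `xy` rows correspond to base indices.
# Returns the realized coordinates/features plus the per-base-cell status
# ("intact" cells survive unsplit/unmerged and anchor landmark selection).
realize_side <- function(xy, feats, cfg) {
  n <- nrow(xy)
  base_index <- seq_len(n)
  keep <- stats::runif(n) >= cfg$dropout_rate
  xy <- xy[keep, , drop = FALSE]
  feats <- feats[keep, , drop = FALSE]
  base_index <- base_index[keep]
  status <- rep("intact", length(base_index))
  m <- nrow(xy)
  # under-segmentation: fuse a cell with its nearest surviving neighbor
  if (cfg$merge_rate > 0 && m >= 4L) {
    n_merge <- stats::rbinom(1, m, cfg$merge_rate)
    if (n_merge > 0) {
      cand <- sample(m, min(n_merge, floor(m / 2)))
      alive <- rep(TRUE, m)
      d2 <- pairwise_sq_dist(xy, xy)
      diag(d2) <- Inf
      for (i in cand) {
        if (!alive[i]) next
        j <- which.min(ifelse(alive, d2[i, ], Inf))
        if (!alive[j] || j == i) next
        xy[i, ] <- (xy[i, ] + xy[j, ]) / 2
        feats[i, ] <- (feats[i, ] + feats[j, ]) / 2
        status[i] <- "merged"
        alive[j] <- FALSE
      }
      xy <- xy[alive, , drop = FALSE]
      feats <- feats[alive, , drop = FALSE]
      base_index <- base_index[alive]
      status <- status[alive]
      m <- nrow(xy)
    }
  }
  # over-segmentation: one cell becomes two children offset +/- 2 um
  if (cfg$split_rate > 0 && m >= 1L) {
    do_split <- stats::runif(m) < cfg$split_rate & status == "intact"
    if (any(do_split)) {
      si <- which(do_split)
      ang <- stats::runif(length(si), 0, 2 * pi)
      off <- cbind(2 * cos(ang), 2 * sin(ang))
      child1 <- xy[si, , drop = FALSE] + off
      child2 <- xy[si, , drop = FALSE] - off
      cf <- feats[si, , drop = FALSE]
      cf$area <- cf$area / 2
      cf$perimeter <- cf$perimeter / sqrt(2)
      status[si] <- "split"
      xy <- rbind(xy[-si, , drop = FALSE], child1, child2)
      feats <- rbind(feats[-si, , drop = FALSE], cf, cf)
      base_index <- c(base_index[-si], base_index[si], base_index[si])
      status <- c(status[-si], rep("split", 2L * length(si)))
    }
  }
  if (cfg$jitter_sd > 0) {
    xy <- xy + matrix(stats::rnorm(length(xy), 0, cfg$jitter_sd), ncol = 2L)
  }
  feats <- perturb_features(feats, cfg$feature_noise_sd, cfg$feature_decorrelate)
  list(xy = xy, feats = feats, base_index = base_index, status = status)
}

# Greedy farthest-point selection of k indices from xy (deterministic).
farthest_points <- function(xy, k) {
  n <- nrow(xy)
  ctr <- colMeans(xy)
  sel <- which.max(rowSums(sweep(xy, 2, ctr)^2))
  d2min <- pairwise_sq_dist(xy, xy[sel, , drop = FALSE])[, 1]
  while (length(sel) < k) {
    nxt <- which.max(d2min)
    sel <- c(sel, nxt)
    d2min <- pmin(d2min, pairwise_sq_dist(xy, xy[nxt, , drop = FALSE])[, 1])
  }
  sel
}

#' Generate a synthetic TMA-core pair with known ground truth
#'
#' Produces a source cell table, a target cell table (the source pushed
#' through the ground-truth transform, then independently perturbed),
#' landmark pairs taken from mutually distant cells surviving intact on both
#' sides (landmark coordinates are pre-jitter, so they map exactly under the
#' returned transform), and the transform itself. Both tables carry a
#' `base_index` feature identifying the underlying base cell, which lets
#' tests score match correctness.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `core_pair` with elements `source`, `target`
#'   (`cell_table`s), `landmarks` (`landmark_pairs`), `transform`
#'   (`rigid_transform`), and `config`.
#' @export
generate_core_pair <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  for (attempt in 0:4) {
    out <- with_seed(config$seed + attempt * 100003L, generate_core_pair_once(config))
    if (!is.null(out)) {
      if (attempt > 0) {
        warning(sprintf("core regeneration needed (%d attempt(s)) to obtain %d shared landmarks",
          attempt, config$n_landmarks
        ), call. = FALSE)
      }
      return(out)
    }
  }
  stop("could not generate ", config$n_landmarks,
    " shared surviving cells after 5 attempts; relax the perturbation rates",
    call. = FALSE
  )
}

generate_core_pair_once <- function(cfg) {
  n <- cfg$n_cells
  r <- cfg$core_radius
  n_bg <- round(n * (1 - cfg$cluster_fraction))
  n_cl <- n - n_bg
  # uniform-in-disc background
  rad <- r * sqrt(stats::runif(n_bg))
  ang <- stats::runif(n_bg, 0, 2 * pi)
  bg <- cbind(rad * cos(ang), rad * sin(ang))
  # Gaussian hotspots, resampled into the disc
  ctr_rad <- 0.6 * r * sqrt(stats::runif(cfg$n_clusters))
  ctr_ang <- stats::runif(cfg$n_clusters, 0, 2 * pi)
  centers <- cbind(ctr_rad * cos(ctr_ang), ctr_rad * sin(ctr_ang))
  assign <- sample(cfg$n_clusters, n_cl, replace = TRUE)
  cl <- centers[assign, , drop = FALSE] +
    matrix(stats::rnorm(2 * n_cl, 0, cfg$cluster_sd), ncol = 2L)
  out_of_disc <- rowSums(cl^2) > r^2
  while (any(out_of_disc)) {
    k <- sum(out_of_disc)
    cl[out_of_disc, ] <- centers[assign[out_of_disc], , drop = FALSE] +
      matrix(stats::rnorm(2 * k, 0, cfg$cluster_sd), ncol = 2L)
    out_of_disc <- rowSums(cl^2) > r^2
  }
  base_xy <- rbind(bg, cl)
  base_feats <- draw_base_features(n)
  target_base_xy <- apply_transform(cfg$true_transform, base_xy)
  src <- realize_side(base_xy, base_feats, cfg)
  tgt <- realize_side(target_base_xy, base_feats, cfg)
  intact_src <- src$base_index[src$status == "intact"]
  intact_tgt <- tgt$base_index[tgt$status == "intact"]
  shared <- intersect(intact_src, intact_tgt)
  if (length(shared) < cfg$n_landmarks) {
    return(NULL)
  }
  lm_idx <- shared[farthest_points(base_xy[shared, , drop = FALSE], cfg$n_landmarks)]
  landmarks <- landmark_pairs(
    base_xy[lm_idx, , drop = FALSE],
    target_base_xy[lm_idx, , drop = FALSE]
  )
  source_tab <- cell_table(
    src$xy,
    features = cbind(src$feats, base_index = src$base_index),
    cell_id = sprintf("he_%05d", seq_len(nrow(src$xy))),
    modality = "HE"
  )
  target_tab <- cell_table(
    tgt$xy,
    features = cbind(tgt$feats, base_index = tgt$base_index),
    cell_id = sprintf("mxif_%05d", seq_len(nrow(tgt$xy))),
    modality = "MxIF"
  )
  structure(
    list(
      source = source_tab, target = target_tab,
      landmarks = landmarks, transform = cfg$true_transform, config = cfg
    ),
    class = "core_pair"
  )
}
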
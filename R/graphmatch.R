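# Graph-matching refinement of the CPD alignment.
#
# Small subgraphs are sampled from cell-dense regions of the source cloud,
# mapped through the CPD transform to locate the corresponding target
# window, matched node-to-node with reweighted random walks on the
# association graph, discretized with the Hungarian algorithm, and finally
# filtered with locality-preserving matching. The surviving pairs, pooled
# over all windows, determine the refined transform.

#' Graph-matching configuration
#'
#' @param source_window Side length (um) of the square sampling window in the
#'   source modality (default 50).
#' @param target_window Side length (um) of the corresponding target window
#'   (default 150); larger so the true counterparts survive residual CPD
#'   error at the window location.
#' @param edge_threshold Graph edges connect cells closer than this (um,
#'   default 15).
#' @param kde_bandwidth Gaussian KDE bandwidth (um) for the cell-density
#'   ranking (default 25, half the source window).
#' @param kde_density_cutoff Normalized density above which cells are
#'   eligible window centers (default 0.5).
#' @param n_windows Number of sampling windows per core (default 8).
#' @param max_nodes_per_window Node cap per subgraph; larger windows are
#'   down-sampled (seeded) to keep the association graph tractable.
#' @param node_features Feature columns used for node affinity.
#' @param node_feature_scale Gaussian kernel scale on standardized node
#'   feature differences.
#' @param edge_length_scale Gaussian kernel scale (um) on edge-length
#'   differences.
#' @param candidate_radius Candidate gating radius (um): a target node is an
#'   admissible match for a source node only if it lies within this distance
#'   of the source node's CPD-mapped position. This carries the positional
#'   prior already implicit in the window construction down to node level,
#'   keeping the association graph discriminative; set `Inf` to disable.
#' @param rrwm_alpha Weight of the affinity-driven walk in the update; the
#'   remaining `1 - rrwm_alpha` goes to the reweighted (inflated,
#'   Sinkhorn-normalized) jump distribution.
#' @param rrwm_beta Reweighting inflation factor.
#' @param rrwm_max_iter,rrwm_tol Iteration cap and convergence tolerance of
#'   the RRWM solver.
#' @param sinkhorn_iterations Row/column normalization sweeps per
#'   reweighting step.
#' @param lpm_k Neighborhood size of the locality-preserving filter.
#' @param lpm_lambda1,lpm_lambda2 Cost thresholds of the two LPM passes
#'   (permissive, then strict among survivors).
#' @return A list of class `graphmatch_config`.
#' @export
graphmatch_config <- function(source_window = 50, target_window = 150,
                              edge_threshold = 15, kde_bandwidth = 25,
                              kde_density_cutoff = 0.5, n_windows = 8L,
                              max_nodes_per_window = 250L,
                              node_features = c("perimeter", "solidity"),
                              node_feature_scale = 1, edge_length_scale = 2,
                              candidate_radius = 8,
                              rrwm_alpha = 0.2, rrwm_beta = 30,
                              rrwm_max_iter = 300L, rrwm_tol = 1e-6,
                              sinkhorn_iterations = 10L,
                              lpm_k = 8L, lpm_lambda1 = 6, lpm_lambda2 = 4) {
  if (target_window < source_window) {
    stop("`target_window` must be >= `source_window`", call. = FALSE)
  }
  lens <- c(source_window, target_window, edge_threshold, kde_bandwidth)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("window, edge and bandwidth lengths must be positive", call. = FALSE)
  }
  if (lpm_k < 1L) stop("`lpm_k` must be >= 1", call. = FALSE)
  structure(
    list(
      source_window = source_window, target_window = target_window,
      edge_threshold = edge_threshold, kde_bandwidth = kde_bandwidth,
      kde_density_cutoff = kde_density_cutoff, n_windows = as.integer(n_windows),
      max_nodes_per_window = as.integer(max_nodes_per_window),
      node_features = node_features, node_feature_scale = node_feature_scale,
      edge_length_scale = edge_length_scale, candidate_radius = candidate_radius,
      rrwm_alpha = rrwm_alpha,
      rrwm_beta = rrwm_beta, rrwm_max_iter = as.integer(rrwm_max_iter),
      rrwm_tol = rrwm_tol, sinkhorn_iterations = as.integer(sinkhorn_iterations),
      lpm_k = as.integer(lpm_k), lpm_lambda1 = lpm_lambda1, lpm_lambda2 = lpm_lambda2
    ),
    class = "graphmatch_config"
  )
}

#' Normalized kernel density at each cell
#'
#' Gaussian kernel density estimate evaluated at every centroid, min-max
#' normalized to `[0, 1]`. Dense subregions carry the clearest tissue
#' architecture, so window sampling prefers high-density cells; sparse
#' regions are more exposed to segmentation noise.
#'
#' @param cells A `cell_table` or coordinate matrix (um).
#' @param bandwidth Kernel bandwidth in micrometers.
#' @return A numeric vector of per-cell densities in `[0, 1]`.
#' @export
kde_density <- function(cells, bandwidth = 25) {
  xy <- as_xy(cells)
  n <- nrow(xy)
  if (n < 2L) {
    warning("fewer than 2 cells; returning all-ones density", call. = FALSE)
    return(rep(1, n))
  }
  if (bandwidth <= 0) stop("`bandwidth` must be > 0", call. = FALSE)
  d <- unname(rowSums(exp(-pairwise_sq_dist(xy, xy) / (2 * bandwidth^2))))
  rng <- range(d)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(rep(1, n))
  }
  (d - rng[1]) / (rng[2] - rng[1])
}

#' Sample window centers from dense regions
#'
#' Draws up to `n_windows` cells (without replacement, seeded) from those
#' whose normalized density reaches `kde_density_cutoff`; the selected cell
#' centroids become window centers. If no cell passes the cutoff, the top
#' density decile is used instead with a warning.
#'
#' @param cells A `cell_table` or coordinate matrix.
#' @param densities Per-cell normalized densities from [kde_density()].
#' @param config A [graphmatch_config()].
#' @param seed Integer seed making the draw reproducible.
#' @return A k x 2 matrix of window centers (um), k <= `n_windows`.
#' @export
sample_windows <- function(cells, densities, config = graphmatch_config(), seed = 1L) {
  xy <- as_xy(cells)
  stopifnot(length(densities) == nrow(xy))
  eligible <- which(densities >= config$kde_density_cutoff)
  if (!length(eligible)) {
    warning("no cell reaches the density cutoff; falling back to the top decile",
      call. = FALSE
    )
    eligible <- which(densities >= stats::quantile(densities, 0.9))
  }
  k <- min(config$n_windows, length(eligible))
  picked <- with_seed(seed, {
    if (length(eligible) == 1L) eligible else sample(eligible, k)
  })
  xy[picked, , drop = FALSE]
}

#' Build a proximity subgraph inside a square window
#'
#' Nodes are the cells inside the axis-aligned square of side `window`
#' centered at `center` (down-sampled to `max_nodes` with a seeded draw when
#' over-full); undirected edges connect node pairs closer than
#' `edge_threshold`, storing the edge length.
#'
#' @param cells A `cell_table`.
#' @param center Length-2 window center (um).
#' @param window Window side length (um).
#' @param edge_threshold Edge distance threshold (um).
#' @param max_nodes Node cap.
#' @param seed Seed for the down-sampling draw.
#' @return A list of class `cell_graph`: `idx` (row indices into `cells`),
#'   `xy`, `features` (data frame), `edges` (matrix with columns `i`, `j`,
#'   `length`; local node indices).
#' @export
build_subgraph <- function(cells, center, window, edge_threshold,
                           max_nodes = 120L, seed = 1L) {
  if (window <= 0) stop("`window` must be > 0", call. = FALSE)
  xy <- as_xy(cells)
  half <- window / 2
  inside <- which(abs(xy[, 1] - center[1]) <= half & abs(xy[, 2] - center[2]) <= half)
  if (length(inside) > max_nodes) {
    inside <- sort(with_seed(seed, sample(inside, max_nodes)))
  }
  sub_xy <- xy[inside, , drop = FALSE]
  nn <- length(inside)
  edges <- matrix(numeric(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "length")))
  if (nn >= 2L && edge_threshold > 0) {
    d2 <- pairwise_sq_dist(sub_xy, sub_xy)
    hit <- which(upper.tri(d2) & d2 < edge_threshold^2, arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- cbind(i = hit[, 1], j = hit[, 2], length = sqrt(d2[hit]))
    }
  }
  feats <- if (inherits(cells, "cell_table")) {
    as.data.frame(cells)[inside, cell_features(cells), drop = FALSE]
  } else {
    data.frame(row.names = seq_len(nn))
  }
  structure(
    list(idx = inside, xy = sub_xy, features = feats, edges = edges),
    class = "cell_graph"
  )
}

#' Map a window center through a transform
#'
#' The target-side subgraph is built around the CPD image of the source
#' window center, so the two subgraphs cover corresponding tissue.
#'
#' @param center Length-2 point (um).
#' @param transform A `rigid_transform`.
#' @return Length-2 mapped point.
#' @export
map_window_center <- function(center, transform) {
  as.numeric(apply_transform(transform, matrix(center, ncol = 2L)))
}

#' Association affinity structure for two subgraphs
#'
#' Node affinity is a Gaussian kernel on the difference of standardized node
#' features (perimeter and solidity by default; standardization uses the
#' pooled mean/sd of both graphs so the same physical cell scores near 1
#' across graphs). Edge affinity is a Gaussian kernel on edge-length
#' differences. Both are assembled into the sparse association (Lawler)
#' matrix `K` indexed by candidate assignments `(i, a)`: diagonal entries
#' carry node affinities, off-diagonal entries pair source edge `(i, j)`
#' with target edge `(a, b)`.
#'
#' @param source,target `cell_graph` objects.
#' @param node_features Feature columns used for node affinity.
#' @param node_feature_scale,edge_length_scale Kernel scales.
#' @param mapped_source_xy Optional n_source x 2 matrix of source node
#'   positions mapped into target space (e.g. through the CPD transform);
#'   required for candidate gating.
#' @param candidate_radius Admissibility radius (um) around each mapped
#'   source position; `Inf` admits every pair.
#' @return A list of class `gm_affinity` with the sparse association matrix
#'   `K`, dimensions `n_source`, `n_target`, the dense `node_affinity`
#'   matrix and the logical candidate `mask`.
#' @export
affinity_matrix <- function(source, target,
                            node_features = c("perimeter", "solidity"),
                            node_feature_scale = 1, edge_length_scale = 2,
                            mapped_source_xy = NULL, candidate_radius = Inf) {
  n1 <- nrow(source$xy)
  n2 <- nrow(target$xy)
  if (n1 == 0L || n2 == 0L) stop("both graphs must be non-empty", call. = FALSE)
  for (f in node_features) {
    if (!f %in% names(source$features) || !f %in% names(target$features)) {
      stop("node feature `", f, "` missing from the cell tables", call. = FALSE)
    }
  }
  fs <- as.matrix(source$features[node_features])
  ft <- as.matrix(target$features[node_features])
  pooled <- rbind(fs, ft)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < .Machine$double.eps] <- 1
  fs <- sweep(sweep(fs, 2, mu), 2, sdv, "/")
  ft <- sweep(sweep(ft, 2, mu), 2, sdv, "/")
  d2 <- pairwise_sq_dist(fs, ft)
  node_aff <- exp(-d2 / (2 * node_feature_scale^2))
  mask <- matrix(TRUE, n1, n2)
  if (is.finite(candidate_radius)) {
    if (is.null(mapped_source_xy)) {
      stop("candidate gating needs `mapped_source_xy`", call. = FALSE)
    }
    mask <- pairwise_sq_dist(as_xy(mapped_source_xy), target$xy) <= candidate_radius^2
    # a source node with no admissible target keeps its full candidate row,
    # so it can still be matched (and later rejected by the locality filter)
    empty <- rowSums(mask) == 0L
    mask[empty, ] <- TRUE
  }
  idx <- function(i, a) (i - 1L) * n2 + a
  allowed <- which(t(mask)) # in idx() order
  rows <- idx(rep(seq_len(n1), each = n2), rep(seq_len(n2), times = n1))[allowed]
  vals <- as.numeric(t(node_aff))[allowed]
  es <- source$edges
  et <- target$edges
  if (nrow(es) && nrow(et)) {
    g <- expand.grid(e = seq_len(nrow(es)), f = seq_len(nrow(et)))
    ea <- exp(-(es[g$e, "length"] - et[g$f, "length"])^2 / (2 * edge_length_scale^2))
    i <- es[g$e, "i"]; j <- es[g$e, "j"]
    a <- et[g$f, "i"]; b <- et[g$f, "j"]
    # the four assignment combinations consistent with undirected edges
    r2 <- c(idx(i, a), idx(j, b), idx(i, b), idx(j, a))
    c2 <- c(idx(j, b), idx(i, a), idx(j, a), idx(i, b))
    e4 <- rep(ea, 4L)
    ok <- t(mask)[r2] & t(mask)[c2]
    K <- Matrix::sparseMatrix(
      i = c(rows, r2[ok]), j = c(rows, c2[ok]), x = c(vals, e4[ok]),
      dims = c(n1 * n2, n1 * n2)
    )
  } else {
    K <- Matrix::sparseMatrix(i = rows, j = rows, x = vals, dims = c(n1 * n2, n1 * n2))
  }
  structure(
    list(K = K, n_source = n1, n_target = n2, node_affinity = node_aff, mask = mask),
    class = "gm_affinity"
  )
}

#' Reweighted random-walk soft graph matching
#'
#' Power iteration of the random walk on the association graph, interleaved
#' with an inflation step and Sinkhorn row/column normalization that pushes
#' the walk distribution toward the one-to-one matching polytope; a restart
#' term mixes the affinity-driven walk with the reweighted jump
#' distribution. Iterates until the assignment vector moves less than
#' `rrwm_tol` or the cap is hit (the current iterate is then returned with a
#' warning).
#'
#' @param affinity A `gm_affinity` from [affinity_matrix()].
#' @param config A [graphmatch_config()] supplying the solver parameters.
#' @return A soft assignment matrix (`n_source` x `n_target`, entries in
#'   `[0, 1]`, scaled to unit maximum) with attribute `converged`.
#' @export
rrwm_match <- function(affinity, config = graphmatch_config()) {
  stopifnot(inherits(affinity, "gm_affinity"))
  n1 <- affinity$n_source
  n2 <- affinity$n_target
  nv <- n1 * n2
  K <- affinity$K
  mask0 <- affinity$mask %||% matrix(TRUE, n1, n2)
  # start the walk from the admissible node affinities rather than uniform:
  # the jump reweighting is exponential in the current iterate, so a
  # feature-informed start avoids locking onto degree noise
  x0 <- as.numeric(t(affinity$node_affinity * mask0))
  x <- if (sum(x0) > 0) x0 / sum(x0) else rep(1 / nv, nv)
  alpha <- config$rrwm_alpha
  beta <- config$rrwm_beta
  converged <- FALSE
  if (sum(K@x) <= 0) {
    soft <- matrix(1 / nv, n1, n2)
    attr(soft, "converged") <- TRUE
    return(soft)
  }
  mask <- mask0
  for (it in seq_len(config$rrwm_max_iter)) {
    x1 <- as.numeric(K %*% x)
    s <- sum(x1)
    if (s <= 0) break
    x1 <- x1 / s
    Ymat <- matrix(exp(beta * x1 / max(x1)), n1, n2, byrow = TRUE)
    Ymat[!mask] <- 0
    for (k in seq_len(config$sinkhorn_iterations)) {
      rs <- rowSums(Ymat)
      Ymat <- Ymat / ifelse(rs > 0, rs, 1)
      cs <- colSums(Ymat)
      Ymat <- sweep(Ymat, 2, ifelse(cs > 0, cs, 1), "/")
    }
    y <- as.numeric(t(Ymat))
    y <- y / sum(y)
    x_new <- alpha * x1 + (1 - alpha) * y
    x_new <- x_new / sum(x_new)
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < config$rrwm_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("RRWM did not converge within the iteration cap; returning current iterate",
      call. = FALSE
    )
  }
  soft <- matrix(x, n1, n2, byrow = TRUE)
  soft <- soft / max(soft)
  attr(soft, "converged") <- converged
  soft
}

#' Discretize a soft assignment into one-to-one pairs
#'
#' Hungarian maximum-total-score assignment on the soft matrix; with a
#' rectangular matrix the surplus nodes of the larger side stay unpaired.
#'
#' @param soft A soft assignment matrix.
#' @return Integer matrix with columns `source`, `target` (local node
#'   indices), ordered by `source`.
#' @export
discretize <- function(soft) {
  pairs <- solve_assignment(soft)
  colnames(pairs) <- c("source", "target")
  pairs
}

# Locality cost of each putative pair: number of the K nearest neighbors (in
# either space, among the putative pairs themselves) not shared with the
# other space. A correct pair in a coherently moving neighborhood has cost 0.
lpm_cost <- function(src, tgt, k) {
  n <- nrow(src)
  ds <- pairwise_sq_dist(src, src)
  dt <- pairwise_sq_dist(tgt, tgt)
  diag(ds) <- Inf
  diag(dt) <- Inf
  cost <- numeric(n)
  for (i in seq_len(n)) {
    ns <- order(ds[i, ])[seq_len(k)]
    nt <- order(dt[i, ])[seq_len(k)]
    cost[i] <- 2 * (k - length(intersect(ns, nt)))
  }
  cost
}

#' Locality-preserving match filtering
#'
#' Keeps the putative pairs whose spatial neighborhoods are consistent
#' across the two point sets. Two passes: a permissive pass over all pairs
#' (cost threshold `lambda1`), then a strict pass (`lambda2`) with
#' neighborhoods recomputed among first-pass survivors only, so clustered
#' false matches cannot vouch for each other. Under a global similarity
#' transform with no noise every neighborhood is preserved and all pairs are
#' kept.
#'
#' @param source_xy,target_xy Coordinates (um) of the putative pairs in
#'   source and target space (row i of each is one pair).
#' @param k Neighborhood size.
#' @param lambda1,lambda2 Cost thresholds of the two passes.
#' @return A logical vector: `TRUE` for kept pairs.
#' @export
lpm_filter <- function(source_xy, target_xy, k = 8L, lambda1 = 6, lambda2 = 4) {
  src <- as_xy(source_xy)
  tgt <- as_xy(target_xy)
  stopifnot(nrow(src) == nrow(tgt))
  n <- nrow(src)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (n < k + 1L) {
    warning("fewer putative pairs than k + 1; locality filter undefined, keeping all",
      call. = FALSE
    )
    return(rep(TRUE, n))
  }
  keep1 <- lpm_cost(src, tgt, k) <= lambda1
  if (sum(keep1) < k + 1L) {
    return(keep1)
  }
  surv <- which(keep1)
  keep2 <- lpm_cost(src[surv, , drop = FALSE], tgt[surv, , drop = FALSE], k) <= lambda2
  kept <- rep(FALSE, n)
  kept[surv[keep2]] <- TRUE
  kept
}

#' Final transform from the surviving cell pairs
#'
#' Similarity fit (scale fixed to 1) on the locality-filtered pairs pooled
#' across windows; this is the pipeline's refined transform. Because a small
#' fraction of survivors can still be near-miss matches (a neighboring cell
#' a few micrometers away), the fit is made robust by iterative residual
#' trimming: pairs whose residual exceeds `trim_sigma` robust standard
#' deviations (Rayleigh-calibrated from the residual median) are dropped and
#' the transform refit, until stable.
#'
#' @param source_xy,target_xy Coordinates (um) of the kept pairs.
#' @param trim_sigma Residual trimming threshold in robust sigmas; `Inf`
#'   disables trimming.
#' @param max_rounds Maximum trimming iterations.
#' @return A `rigid_transform` with attribute `n_pairs_used`.
#' @export
refine_transform <- function(source_xy, target_xy, trim_sigma = 3, max_rounds = 5L) {
  src <- as_xy(source_xy)
  tgt <- as_xy(target_xy)
  if (nrow(src) < 2L) {
    stop("refinement failed: fewer than 2 kept pairs", call. = FALSE)
  }
  use <- rep(TRUE, nrow(src))
  tf <- fit_similarity(src, tgt, fix_scale = TRUE)
  if (is.finite(trim_sigma)) {
    for (round in seq_len(max_rounds)) {
      resid <- sqrt(rowSums((tgt - apply_transform(tf, src))^2))
      # median of a Rayleigh(sigma) is sigma * sqrt(log 4)
      sigma_hat <- stats::median(resid[use]) / sqrt(log(4))
      keep <- resid <= trim_sigma * max(sigma_hat, .Machine$double.eps) | resid == 0
      if (sum(keep) < 2L || all(keep == use)) break
      use <- keep
      tf <- fit_similarity(src[use, , drop = FALSE], tgt[use, , drop = FALSE],
        fix_scale = TRUE
      )
    }
  }
  attr(tf, "n_pairs_used") <- sum(use)
  tf
}

#' Model-free alignment cost of a transform
#'
#' Trimmed mean nearest-neighbor distance from the mapped source cells to
#' the target cells. Computable without any ground truth, it lets the
#' pipeline compare candidate transforms (e.g. CPD versus the graph-matching
#' refinement); the trimming makes it insensitive to cells present in one
#' modality only.
#'
#' @param source,target `cell_table`s or coordinate matrices (um).
#' @param transform A `rigid_transform` mapping source into target space.
#' @param trim Fraction of smallest nearest-neighbor distances averaged
#'   (default 0.7).
#' @return Mean trimmed nearest-neighbor distance (um).
#' @export
alignment_cost <- function(source, target, transform, trim = 0.7) {
  sxy <- apply_transform(transform, as_xy(source))
  txy <- as_xy(target)
  n <- nrow(sxy)
  nn <- numeric(n)
  step <- max(1L, floor(2e6 / max(1L, nrow(txy))))
  for (start in seq(1L, n, by = step)) {
    rows <- start:min(start + step - 1L, n)
    d2 <- pairwise_sq_dist(sxy[rows, , drop = FALSE], txy)
    nn[rows] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  k <- max(1L, floor(trim * n))
  mean(sort(nn)[seq_len(k)])
}

#' Windowed graph matching between two aligned cell tables
#'
#' The full refinement stage: ranks source cells by kernel density, samples
#' window centers from the dense regions, builds a source subgraph (side
#' `source_window`) and a CPD-mapped target subgraph (side `target_window`)
#' per window, matches them with RRWM + Hungarian, pools the one-to-one
#' pairs over windows (deduplicated, keeping the highest affinity) and
#' applies the locality-preserving filter.
#'
#' @param source,target `cell_table`s in micrometers.
#' @param cpd_transform The coarse `rigid_transform` from [cpd_align()].
#' @param config A [graphmatch_config()].
#' @param seed Integer seed controlling window sampling and down-sampling.
#' @return A data frame of class `match_set` with columns `source_id`,
#'   `target_id`, `source_idx`, `target_idx`, `affinity`, `kept_by_lpm`,
#'   plus attribute `n_windows_used`.
#' @export
match_cells <- function(source, target, cpd_transform,
                        config = graphmatch_config(), seed = 1L) {
  stopifnot(inherits(source, "cell_table"), inherits(target, "cell_table"))
  dens <- kde_density(source, config$kde_bandwidth)
  centers <- sample_windows(source, dens, config, seed = seed)
  acc <- vector("list", nrow(centers))
  used <- 0L
  for (wi in seq_len(nrow(centers))) {
    sg <- build_subgraph(source, centers[wi, ], config$source_window,
      config$edge_threshold, config$max_nodes_per_window,
      seed = seed + wi
    )
    if (length(sg$idx) < 2L) next
    tc <- map_window_center(centers[wi, ], cpd_transform)
    tg <- build_subgraph(target, tc, config$target_window,
      config$edge_threshold, config$max_nodes_per_window,
      seed = seed + 1000L + wi
    )
    if (length(tg$idx) < 2L) next
    aff <- affinity_matrix(sg, tg,
      node_features = config$node_features,
      node_feature_scale = config$node_feature_scale,
      edge_length_scale = config$edge_length_scale,
      mapped_source_xy = apply_transform(cpd_transform, sg$xy),
      candidate_radius = config$candidate_radius
    )
    soft <- rrwm_match(aff, config)
    pairs <- discretize(soft)
    if (!nrow(pairs)) next
    used <- used + 1L
    acc[[wi]] <- data.frame(
      source_idx = sg$idx[pairs[, "source"]],
      target_idx = tg$idx[pairs[, "target"]],
      affinity = soft[pairs]
    )
  }
  pooled <- do.call(rbind, acc)
  if (is.null(pooled) || !nrow(pooled)) {
    out <- data.frame(
      source_id = character(0), target_id = character(0),
      source_idx = integer(0), target_idx = integer(0),
      affinity = numeric(0), kept_by_lpm = logical(0)
    )
    class(out) <- c("match_set", "data.frame")
    attr(out, "n_windows_used") <- used
    return(out)
  }
  # dedupe pairs seen in several windows, keeping the best affinity
  key <- paste(pooled$source_idx, pooled$target_idx)
  pooled <- pooled[order(key, -pooled$affinity), , drop = FALSE]
  pooled <- pooled[!duplicated(paste(pooled$source_idx, pooled$target_idx)), , drop = FALSE]
  pooled <- pooled[order(pooled$source_idx, pooled$target_idx), , drop = FALSE]
  sxy <- as_xy(source)[pooled$source_idx, , drop = FALSE]
  txy <- as_xy(target)[pooled$target_idx, , drop = FALSE]
  kept <- lpm_filter(sxy, txy,
    k = config$lpm_k,
    lambda1 = config$lpm_lambda1, lambda2 = config$lpm_lambda2
  )
  out <- data.frame(
    source_id = source$cell_id[pooled$source_idx],
    target_id = target$cell_id[pooled$target_idx],
    source_idx = pooled$source_idx,
    target_idx = pooled$target_idx,
    affinity = pooled$affinity,
    kept_by_lpm = kept
  )
  rownames(out) <- NULL
  class(out) <- c("match_set", "data.frame")
  attr(out, "n_windows_used") <- used
  out
}
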
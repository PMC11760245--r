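# Rigid Coherent Point Drift: coarse alignment of the two centroid clouds.
#
# One cloud (the moving set) parameterizes the centroids of an isotropic
# Gaussian mixture; the other (fixed set) is treated as data drawn from that
# mixture plus a uniform outlier component. EM alternates soft
# correspondence estimation (E-step) with a closed-form rigid update of
# rotation, translation and mixture variance (M-step). With both clouds in
# micrometers the scale is fixed at 1.

#' CPD configuration
#'
#' @param w Uniform-outlier weight in `[0, 1)`. Accounts for cells present in
#'   one modality only (dropout, segmentation disagreement).
#' @param max_iterations EM iteration cap.
#' @param tolerance Relative change in the negative log-likelihood below
#'   which EM stops.
#' @param fixed_scale Keep the scale clamped at 1 (the operating mode once
#'   both clouds are in micrometers).
#' @param restarts Probe the four coarse orientations (0, 90, 180, 270
#'   degrees) for a few iterations each and continue from the best, since EM
#'   is local and tissue cores may be arbitrarily rotated.
#' @param probe_iterations EM iterations spent on each orientation probe.
#' @param supercell_cap Point-count above which both clouds are reduced to
#'   proximity "super-cells" before alignment (whole-slide scalability).
#' @param supercell_linkage Linkage distance (um) used for that reduction.
#' @return A list of class `cpd_config`.
#' @export
cpd_config <- function(w = 0.1, max_iterations = 150L, tolerance = 1e-6,
                       fixed_scale = TRUE, restarts = TRUE,
                       probe_iterations = 10L,
                       supercell_cap = 20000L, supercell_linkage = 20) {
  if (!is.numeric(w) || w < 0 || w >= 1) stop("`w` must lie in [0, 1)", call. = FALSE)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  structure(
    list(
      w = w, max_iterations = as.integer(max_iterations), tolerance = tolerance,
      fixed_scale = isTRUE(fixed_scale), restarts = isTRUE(restarts),
      probe_iterations = as.integer(probe_iterations),
      supercell_cap = as.integer(supercell_cap), supercell_linkage = supercell_linkage
    ),
    class = "cpd_config"
  )
}

# One EM chain from a given state. X: fixed (n x 2), Y: moving (m x 2).
# Returns the updated state plus the NLL trace; EM guarantees the trace is
# non-increasing because the M-step maximizes the complete-data bound exactly
# (rotation via determinant-corrected SVD, then translation, then sigma2).
cpd_em <- function(X, Y, R, tvec, sigma2, w, tol, max_iter, scale_free = FALSE) {
  N <- nrow(X)
  M <- nrow(Y)
  D <- 2
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  s <- 1
  floor_hit <- FALSE
  for (it in seq_len(max_iter)) {
    TY <- s * (Y %*% t(R))
    TY[, 1] <- TY[, 1] + tvec[1]
    TY[, 2] <- TY[, 2] + tvec[2]
    D2 <- pairwise_sq_dist(TY, X) # M x N
    G <- exp(-D2 / (2 * sigma2))
    c0 <- (2 * pi * sigma2)^(D / 2) * w * M / ((1 - w) * N)
    den <- colSums(G) + c0
    nll <- -sum(log(den)) - N * log((1 - w) / (M * (2 * pi * sigma2)^(D / 2)))
    trace <- c(trace, nll)
    if (is.finite(prev) && abs(prev - nll) < tol * (abs(prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- nll
    P <- sweep(G, 2, den, "/")
    Np <- sum(P)
    if (Np < .Machine$double.eps) break
    Pt1 <- colSums(P)
    P1 <- rowSums(P)
    mu_x <- as.numeric(crossprod(X, Pt1)) / Np
    mu_y <- as.numeric(crossprod(Y, P1)) / Np
    Xc <- sweep(X, 2, mu_x)
    Yc <- sweep(Y, 2, mu_y)
    A <- crossprod(Xc, crossprod(P, Yc)) # sum P_mn xc_n yc_m^T
    sv <- svd(A)
    C <- diag(c(1, sign(det(sv$u) * det(sv$v))))
    R <- sv$u %*% C %*% t(sv$v)
    trAR <- sum(diag(C) * sv$d)
    yPy <- sum(P1 * rowSums(Yc^2))
    xPx <- sum(Pt1 * rowSums(Xc^2))
    s <- if (scale_free) trAR / yPy else 1
    tvec <- mu_x - s * as.numeric(R %*% mu_y)
    sigma2_new <- (xPx + s^2 * yPy - 2 * s * trAR) / (Np * D)
    if (!is.finite(sigma2_new) || sigma2_new < 1e-10) {
      sigma2 <- max(sigma2_new, 1e-10)
      converged <- TRUE
      floor_hit <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  list(
    R = R, t = tvec, s = s, sigma2 = sigma2, trace = trace,
    iterations = length(trace), converged = converged, floor_hit = floor_hit
  )
}

rot2 <- function(theta) {
  rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
}

cpd_init_sigma2 <- function(X, Y, R, tvec) {
  TY <- Y %*% t(R)
  TY[, 1] <- TY[, 1] + tvec[1]
  TY[, 2] <- TY[, 2] + tvec[2]
  mean(pairwise_sq_dist(TY, X)) / 2
}

#' Align two centroid clouds with rigid Coherent Point Drift
#'
#' Estimates the rigid transform mapping `moving` onto `fixed` by EM on a
#' Gaussian-mixture formulation with a uniform outlier component. Both
#' clouds must already be in micrometers; the returned transform always has
#' `scale = 1` unless `fixed_scale = FALSE` and a rotation block with
#' determinant +1 (reflections are excluded in the M-step).
#'
#' @param moving,fixed `cell_table`s or n x 2 coordinate matrices (um).
#'   `moving` is the H&E-style source, `fixed` the MxIF-style target.
#' @param config A [cpd_config()].
#' @return A list with elements `transform` (a `rigid_transform`) and
#'   `state` (final `sigma2`, iteration count, objective value, the full
#'   negative log-likelihood trace, and convergence flags).
#' @export
cpd_align <- function(moving, fixed, config = cpd_config()) {
  stopifnot(inherits(config, "cpd_config"))
  Y <- as_xy(moving)
  X <- as_xy(fixed)
  if (nrow(Y) < 2L || nrow(X) < 2L) {
    stop("both point sets need at least 2 points", call. = FALSE)
  }
  if (nrow(Y) > config$supercell_cap) {
    Y <- as_xy(supercell_reduce(cell_table(Y), config$supercell_linkage))
  }
  if (nrow(X) > config$supercell_cap) {
    X <- as_xy(supercell_reduce(cell_table(X), config$supercell_linkage))
  }
  mu_x <- colMeans(X)
  mu_y <- colMeans(Y)
  angles <- if (config$restarts) c(0, pi / 2, pi, 3 * pi / 2) else 0
  probes <- lapply(angles, function(a) {
    R0 <- rot2(a)
    t0 <- mu_x - as.numeric(R0 %*% mu_y)
    s2 <- cpd_init_sigma2(X, Y, R0, t0)
    n_probe <- if (length(angles) > 1L) {
      min(config$probe_iterations, config$max_iterations)
    } else {
      config$max_iterations
    }
    cpd_em(X, Y, R0, t0, s2, config$w, config$tolerance, n_probe,
      scale_free = !config$fixed_scale
    )
  })
  finals <- vapply(probes, function(p) p$trace[length(p$trace)], numeric(1))
  best <- probes[[which.min(finals)]]
  remaining <- config$max_iterations - best$iterations
  if (!best$converged && remaining > 0L) {
    cont <- cpd_em(X, Y, best$R, best$t, best$sigma2, config$w,
      config$tolerance, remaining,
      scale_free = !config$fixed_scale
    )
    cont$trace <- c(best$trace, cont$trace)
    cont$iterations <- length(cont$trace)
    best <- cont
  }
  transform <- rigid_transform(
    theta = atan2(best$R[2, 1], best$R[1, 1]),
    scale = best$s,
    dx = best$t[1],
    dy = best$t[2]
  )
  if (best$floor_hit) {
    warning("CPD mixture variance collapsed to its floor; treating as converged",
      call. = FALSE
    )
  }
  state <- list(
    sigma2 = best$sigma2,
    iteration = best$iterations,
    objective = best$trace[length(best$trace)],
    trace = best$trace,
    converged = best$converged
  )
  list(transform = transform, state = state)
}

#' Reduce a cell table to proximity "super-cells"
#'
#' Single-linkage clustering at a fixed linkage distance: any two cells at
#' most `linkage_distance` apart end up in the same cluster (chains merge
#' transitively). Each cluster becomes one pseudo-cell at the member-centroid
#' mean, with numeric features averaged and a `member_count` feature
#' attached. This is the scalability device for whole-slide inputs, where
#' running registration on every cell would be prohibitive.
#'
#' The averaging step can leave two pseudo-cell centroids closer than the
#' linkage distance even when no original member pair was; the reduction is
#' therefore iterated until no further merges occur, which also makes it
#' idempotent.
#'
#' @param cells A `cell_table` or coordinate matrix.
#' @param linkage_distance Linkage threshold in micrometers.
#' @return A `cell_table` of pseudo-cells (never more rows than the input).
#' @export
supercell_reduce <- function(cells, linkage_distance) {
  if (!inherits(cells, "cell_table")) cells <- cell_table(as_xy(cells))
  out <- supercell_reduce_once(cells, linkage_distance)
  while (nrow(out) < nrow(cells)) {
    cells <- out
    out <- supercell_reduce_once(cells, linkage_distance)
  }
  out
}

supercell_reduce_once <- function(cells, linkage_distance) {
  if (!is.numeric(linkage_distance) || linkage_distance <= 0) {
    stop("`linkage_distance` must be > 0", call. = FALSE)
  }
  n <- nrow(cells)
  if (n == 0L) stop("empty cell table", call. = FALSE)
  xy <- as_xy(cells)
  comp <- threshold_components(xy, linkage_distance)
  k <- max(comp)
  cf <- factor(comp, levels = seq_len(k))
  sums_x <- tapply(xy[, 1], cf, mean)
  sums_y <- tapply(xy[, 2], cf, mean)
  feats <- setdiff(cell_features(cells), "member_count")
  fdf <- data.frame(member_count = if ("member_count" %in% names(cells)) {
    # re-reducing super-cells accumulates the original member counts
    as.numeric(tapply(cells[["member_count"]], cf, sum))
  } else {
    as.numeric(tabulate(comp, nbins = k))
  })
  for (f in feats) {
    fdf[[f]] <- as.numeric(tapply(cells[[f]], cf, mean))
  }
  cell_table(
    cbind(as.numeric(sums_x), as.numeric(sums_y)),
    features = fdf,
    cell_id = sprintf("sc_%05d", seq_len(k)),
    modality = attr(cells, "modality") %||% ""
  )
}

# Connected components of the graph linking points at distance <= d, found
# with a bucket grid plus union-find so no full distance matrix is formed.
threshold_components <- function(xy, d) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gx <- floor(xy[, 1] / d)
  gy <- floor(xy[, 2] / d)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  bucket_of <- function(kx, ky) buckets[[paste(kx, ky)]]
  d2 <- d^2
  for (b in names(buckets)) {
    idx <- buckets[[b]]
    kk <- as.numeric(strsplit(b, " ", fixed = TRUE)[[1]])
    # candidates: same bucket plus the 8 surrounding buckets
    cand <- idx
    for (ox in -1:1) {
      for (oy in -1:1) {
        if (ox == 0 && oy == 0) next
        cand <- c(cand, bucket_of(kk[1] + ox, kk[2] + oy))
      }
    }
    cand <- unique(cand)
    for (i in idx) {
      dx <- xy[cand, 1] - xy[i, 1]
      dy <- xy[cand, 2] - xy[i, 2]
      hits <- cand[dx * dx + dy * dy <= d2]
      for (j in hits) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
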
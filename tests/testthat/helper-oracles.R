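# Independent oracles and fixture builders used across the suite.

# All permutations of 1..n as rows (n <= 7).
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L))
  }
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(rep(k, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

# Brute-force maximum-score one-to-one assignment by enumeration
# (rows <= cols required; returns the best total score).
brute_best_assignment_score <- function(score) {
  n <- nrow(score)
  m <- ncol(score)
  stopifnot(n <= m)
  combos <- utils::combn(m, n)
  best <- -Inf
  for (ci in seq_len(ncol(combos))) {
    cols <- combos[, ci]
    for (pi in seq_len(nrow(all_permutations(n)))) {
      p <- all_permutations(n)[pi, ]
      tot <- sum(score[cbind(seq_len(n), cols[p])])
      if (tot > best) best <- tot
    }
  }
  best
}

# Quadratic assignment score x^T K x of a hard pairing on a gm_affinity.
quadratic_score <- function(aff, pairs) {
  x <- numeric(aff$n_source * aff$n_target)
  x[(pairs[, 1] - 1L) * aff$n_target + pairs[, 2]] <- 1
  as.numeric(t(x) %*% (aff$K %*% x))
}

# Best quadratic score over all full permutations (equal-size graphs).
brute_best_permutation_score <- function(aff) {
  n <- aff$n_source
  stopifnot(n == aff$n_target)
  P <- all_permutations(n)
  best <- -Inf
  for (i in seq_len(nrow(P))) {
    s <- quadratic_score(aff, cbind(seq_len(n), P[i, ]))
    if (s > best) best <- s
  }
  best
}

# Random geometric cell graph fixture with plausible morphology features.
random_cell_graph <- function(n, seed, extent = 30, edge_threshold = 15) {
  set.seed(seed)
  xy <- matrix(stats::runif(2 * n, 0, extent), ncol = 2)
  d2 <- as.matrix(stats::dist(xy))^2
  hit <- which(upper.tri(d2) & d2 < edge_threshold^2, arr.ind = TRUE)
  edges <- cbind(i = hit[, 1], j = hit[, 2], length = sqrt(d2[hit]))
  structure(
    list(
      idx = seq_len(n), xy = xy,
      features = data.frame(
        perimeter = stats::rlnorm(n, log(22), 0.2),
        solidity = stats::rbeta(n, 36, 4)
      ),
      edges = edges
    ),
    class = "cell_graph"
  )
}

# Permute a graph's nodes (features and coordinates), rebuilding edges.
permute_graph <- function(g, perm, jitter_sd = 0, edge_threshold = 15) {
  xy <- g$xy[perm, , drop = FALSE]
  if (jitter_sd > 0) xy <- xy + matrix(stats::rnorm(length(xy), 0, jitter_sd), ncol = 2)
  d2 <- as.matrix(stats::dist(xy))^2
  hit <- which(upper.tri(d2) & d2 < edge_threshold^2, arr.ind = TRUE)
  structure(
    list(
      idx = seq_len(nrow(xy)), xy = xy,
      features = g$features[perm, , drop = FALSE],
      edges = cbind(i = hit[, 1], j = hit[, 2], length = sqrt(d2[hit]))
    ),
    class = "cell_graph"
  )
}

as_xy_matrix <- function(tab) cbind(tab$x, tab$y)

deg2rad_test <- function(x) x * pi / 180

# Simple cell table on a jittered grid with features, for IO/graph tests.
grid_cell_table <- function(nx = 10, ny = 10, spacing = 12, seed = 1, modality = "HE") {
  set.seed(seed)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  xy <- cbind(g$x * spacing, g$y * spacing)
  n <- nrow(xy)
  cell_table(
    xy,
    features = data.frame(
      area = stats::rlnorm(n, log(35), 0.25),
      perimeter = stats::rlnorm(n, log(22), 0.15),
      solidity = stats::rbeta(n, 36, 4),
      intensity = stats::rlnorm(n, log(100), 0.4)
    ),
    modality = modality
  )
}
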
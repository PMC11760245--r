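# KDE window sampling, subgraphs, affinities, RRWM matching, Hungarian
# discretization, locality-preserving filtering, refinement fit.

test_that("kernel density matches a brute-force Gaussian sum and ranks sensibly", {
  # 5 fixed points, bandwidth 10: oracle is the direct double loop
  pts <- rbind(c(0, 0), c(5, 0), c(0, 5), c(40, 40), c(6, 4))
  bw <- 10
  oracle <- sapply(seq_len(nrow(pts)), function(i) {
    sum(sapply(seq_len(nrow(pts)), function(j) {
      exp(-sum((pts[i, ] - pts[j, ])^2) / (2 * bw^2))
    }))
  })
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  expect_equal(kde_density(pts, bw), oracle, tolerance = 1e-12)

  # uniform grid: interior roughly constant, corners strictly lower
  g <- expand.grid(x = 0:9, y = 0:9)
  xy <- cbind(g$x, g$y) * 10
  d <- kde_density(xy, 25)
  corner <- which(g$x %in% c(0, 9) & g$y %in% c(0, 9))
  interior <- which(g$x %in% 3:6 & g$y %in% 3:6)
  expect_lt(max(d[corner]), min(d[interior]))

  # one dense cluster plus an isolated point: the isolate is the minimum
  clu <- matrix(rnorm(40, 0, 3), ncol = 2)
  iso <- c(200, 200)
  d2 <- kde_density(rbind(clu, iso), 10)
  expect_equal(d2[21], 0)
})

test_that("window sampling is seeded, honors the cutoff, and falls back", {
  set.seed(5)
  xy <- matrix(runif(200, 0, 300), ncol = 2)
  dens <- kde_density(xy, 25)
  cfg <- graphmatch_config(n_windows = 4)
  c1 <- sample_windows(xy, dens, cfg, seed = 9)
  c2 <- sample_windows(xy, dens, cfg, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(dens[match(
    paste(c1[, 1], c1[, 2]),
    paste(xy[, 1], xy[, 2])
  )] >= cfg$kde_density_cutoff))
  # cutoff 0 admits every cell
  c3 <- sample_windows(xy, dens, graphmatch_config(n_windows = 200, kde_density_cutoff = 0), seed = 1)
  expect_equal(nrow(c3), 100L)
  # impossible cutoff triggers the top-decile fallback
  expect_warning(
    c4 <- sample_windows(xy, dens, graphmatch_config(kde_density_cutoff = 2), seed = 1),
    "decile"
  )
  expect_gt(nrow(c4), 0)
})

test_that("subgraph construction applies the window, cap and edge threshold", {
  # three cells at mutual distances 10, 10, 20: threshold 15 -> 2 edges
  tri <- cell_table(rbind(c(0, 0), c(10, 0), c(20, 0)))
  g <- build_subgraph(tri, c(10, 0), 50, 15)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(g$edges[, "length"], c(10, 10))
  # zero threshold -> no edges
  g0 <- build_subgraph(tri, c(10, 0), 50, 0)
  expect_equal(nrow(g0$edges), 0L)
  # node cap with seeded reproducibility
  set.seed(2)
  many <- cell_table(matrix(runif(400, 0, 40), ncol = 2))
  ga <- build_subgraph(many, c(20, 20), 50, 15, max_nodes = 50, seed = 3)
  gb <- build_subgraph(many, c(20, 20), 50, 15, max_nodes = 50, seed = 3)
  expect_equal(length(ga$idx), 50L)
  expect_identical(ga$idx, gb$idx)
  # cells outside the square are excluded
  expect_true(all(abs(many$x[ga$idx] - 20) <= 25 & abs(many$y[ga$idx] - 20) <= 25))
})

test_that("window centers map through the transform", {
  expect_equal(map_window_center(c(3, 4), rigid_transform(0, 1, 0, 0)), c(3, 4))
  expect_equal(map_window_center(c(3, 4), rigid_transform(0, 1, 10, 0)), c(13, 4))
  expect_equal(map_window_center(c(1, 0), rigid_transform(pi / 2, 1, 0, 0)), c(0, 1),
    tolerance = 1e-12
  )
})

test_that("affinities follow the stated Gaussian kernels", {
  g <- random_cell_graph(6, seed = 17)
  aff <- affinity_matrix(g, g)
  # identical graphs: true-pair node affinities are exactly 1
  expect_equal(diag(aff$node_affinity), rep(1, 6))
  # off-diagonal entries reproduce the kernel recomputed independently
  f <- as.matrix(g$features[c("perimeter", "solidity")])
  pooled <- rbind(f, f)
  fz <- sweep(sweep(f, 2, colMeans(pooled)), 2, apply(pooled, 2, sd), "/")
  expected <- exp(-as.matrix(dist(fz))^2 / 2)
  expect_equal(aff$node_affinity, unname(expected), tolerance = 1e-12)
  # equal-length edge pairs have affinity exactly 1 in the association matrix
  e <- g$edges[1, ]
  i1 <- (e[["i"]] - 1) * 6 + e[["i"]]
  expect_equal(
    as.numeric(aff$K[(e[["i"]] - 1) * 6 + e[["i"]], (e[["j"]] - 1) * 6 + e[["j"]]]),
    1
  )
  # missing node feature -> configuration error naming it
  g2 <- g
  g2$features$solidity <- NULL
  expect_error(affinity_matrix(g2, g), "solidity")
})

test_that("candidate gating masks implausible assignments", {
  g <- random_cell_graph(8, seed = 23, extent = 60)
  aff <- affinity_matrix(g, g, mapped_source_xy = g$xy, candidate_radius = 5)
  expect_true(all(diag(aff$mask)))
  d2 <- as.matrix(dist(g$xy))^2
  expect_identical(unname(aff$mask), unname(d2 <= 25 | matrix(FALSE, 8, 8)))
  expect_error(
    affinity_matrix(g, g, candidate_radius = 5),
    "mapped_source_xy"
  )
})

test_that("RRWM with Hungarian recovers known correspondences", {
  # two identical 3-node path graphs with distinct features -> identity
  path3 <- structure(
    list(
      idx = 1:3, xy = rbind(c(0, 0), c(10, 0), c(20, 0)),
      features = data.frame(perimeter = c(15, 25, 35), solidity = c(0.7, 0.85, 0.95)),
      edges = cbind(i = c(1, 2), j = c(2, 3), length = c(10, 10))
    ),
    class = "cell_graph"
  )
  soft <- rrwm_match(affinity_matrix(path3, path3), graphmatch_config())
  expect_equal(discretize(soft)[, "target"], 1:3)
  # argmax of each row sits on the diagonal
  expect_equal(apply(soft, 1, which.max), 1:3)

  # a known permutation of a 4-node graph is recovered (brute-force oracle)
  g <- random_cell_graph(4, seed = 29)
  perm <- c(3, 1, 4, 2)
  g2 <- permute_graph(g, perm)
  aff <- affinity_matrix(g, g2)
  prs <- discretize(rrwm_match(aff, graphmatch_config()))
  expect_equal(
    quadratic_score(aff, prs),
    brute_best_permutation_score(aff),
    tolerance = 1e-9
  )
  expect_equal(prs[, "target"], match(seq_len(4), perm))

  # single-node graphs give the 1x1 soft matrix [1]
  g1 <- random_cell_graph(1, seed = 31)
  soft1 <- rrwm_match(affinity_matrix(g1, g1), graphmatch_config())
  expect_equal(as.numeric(soft1), 1)
})

test_that("the soft assignment is bounded and reproducible", {
  g <- random_cell_graph(6, seed = 37)
  g2 <- permute_graph(g, sample(6), jitter_sd = 0.5)
  aff <- affinity_matrix(g, g2)
  s1 <- rrwm_match(aff, graphmatch_config())
  s2 <- rrwm_match(aff, graphmatch_config())
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("Hungarian discretization equals brute-force enumeration", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    m <- sample.int(7 - n, 1) + n - 1
    score <- matrix(runif(n * m), n, m)
    prs <- solve_assignment(score)
    expect_equal(nrow(prs), n)
    expect_equal(
      sum(score[prs]),
      brute_best_assignment_score(score),
      tolerance = 1e-9
    )
  }
  # worked 2x2 example: optimum picks the anti-diagonal
  prs <- solve_assignment(rbind(c(1, 2), c(2, 1)))
  expect_equal(unname(prs), rbind(c(1L, 2L), c(2L, 1L)))
  # identity score matrix -> identity pairing
  prs2 <- solve_assignment(diag(3))
  expect_equal(unname(prs2[, 2]), 1:3)
  # rectangular 2x3 -> exactly 2 pairs
  expect_equal(nrow(solve_assignment(matrix(runif(6), 2, 3))), 2L)
})

test_that("locality filtering keeps coherent pairs and drops scrambled ones", {
  set.seed(47)
  n <- 60
  src <- matrix(runif(2 * n, 0, 300), ncol = 2)
  tgt <- apply_transform(rigid_transform(0.4, 1, 30, -50), src)
  # a global similarity with zero noise preserves every neighborhood
  expect_true(all(lpm_filter(src, tgt)))
  # one scrambled pair has a fully inconsistent neighborhood: oracle check
  tgt2 <- tgt
  tgt2[13, ] <- tgt[13, ] + c(180, -150)
  kept <- lpm_filter(src, tgt2)
  expect_false(kept[13])
  expect_true(all(kept[-13]))
  ds <- as.matrix(dist(src))
  dt <- as.matrix(dist(tgt2))
  diag(ds) <- diag(dt) <- Inf
  k <- 8
  cost13 <- 2 * (k - length(intersect(
    order(ds[13, ])[1:k], order(dt[13, ])[1:k]
  )))
  expect_gt(cost13, 6)
  # fewer pairs than k + 1 -> undefined filter, all kept with warning
  expect_warning(k5 <- lpm_filter(src[1:5, ], tgt[1:5, ], k = 8), "keeping all")
  expect_true(all(k5))
})

test_that("refinement fit recovers transforms and survives pre-filtered outliers", {
  set.seed(53)
  src <- matrix(runif(80, 0, 300), ncol = 2)
  tf <- rigid_transform(0.2, 1, 15, -25)
  tgt <- apply_transform(tf, src)
  fit <- refine_transform(src, tgt)
  expect_equal(fit$theta, tf$theta, tolerance = 1e-9)
  expect_equal(c(fit$dx, fit$dy), c(15, -25), tolerance = 1e-9)
  # coincident pairs are degenerate
  expect_error(refine_transform(matrix(1, 3, 2), matrix(2, 3, 2)), "degenerate")
  # 5% gross outliers, LPM-filtered first
  tgt2 <- tgt
  bad <- sample(40, 2)
  tgt2[bad, ] <- matrix(runif(4, 0, 300), ncol = 2)
  kept <- lpm_filter(src, tgt2)
  fit2 <- refine_transform(src[kept, ], tgt2[kept, ])
  expect_lt(abs(fit2$theta - tf$theta) * 180 / pi, 0.1)
  expect_lt(sqrt((fit2$dx - 15)^2 + (fit2$dy + 25)^2), 1)
})

test_that("match_cells pools windows reproducibly and one-to-one per window", {
  pair <- generate_core_pair(synthetic_profile("restained", n_cells = 500, seed = 61))
  cpd <- cpd_align(pair$source, pair$target)
  m1 <- match_cells(pair$source, pair$target, cpd$transform, seed = 4)
  m2 <- match_cells(pair$source, pair$target, cpd$transform, seed = 4)
  expect_identical(m1, m2)
  expect_gt(nrow(m1), 0)
  expect_true(all(m1$affinity >= 0 & m1$affinity <= 1))
  expect_false(any(duplicated(paste(m1$source_idx, m1$target_idx))))
  expect_true(all(m1$kept_by_lpm %in% c(TRUE, FALSE)))
})
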
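# Nearest-cell pairing, feature correlation, regional density/composition.

test_that("nearest pairing classifies N=0, N=1 and N>1 as defined", {
  tab <- grid_cell_table(5, 5, spacing = 20, seed = 3)
  # identical point sets: all N=1 at distance zero
  p <- nearest_pairing(tab, tab, radius = 5)
  expect_true(all(p$n_class == "N=1"))
  expect_true(all(p$distance == 0))
  expect_identical(p$target_id, tab$cell_id)

  # a source cell with no target within the radius is N=0
  far <- tab
  far$x[1] <- far$x[1] + 500
  p2 <- nearest_pairing(far, tab, radius = 5)
  expect_equal(p2$n_class[1], "N=0")
  expect_true(is.na(p2$target_id[1]))

  # two sources nearest to the same target mark it N>1
  dup <- cell_table(
    rbind(as_xy_matrix(tab), c(tab$x[1] + 1, tab$y[1] + 1)),
    features = rbind(
      as.data.frame(tab)[cell_features(tab)],
      as.data.frame(tab)[1, cell_features(tab)]
    ),
    cell_id = c(tab$cell_id, "extra")
  )
  p3 <- nearest_pairing(dup, tab, radius = 5)
  expect_equal(sum(p3$n_class == "N>1"), 2L)
  expect_true(all(p3$target_id[p3$n_class == "N>1"] == tab$cell_id[1]))
})

test_that("feature correlation equals the direct formula on printed pairs", {
  tab <- grid_cell_table(4, 3, spacing = 25, seed = 9)
  tab2 <- tab
  set.seed(10)
  tab2$area <- tab$area * exp(rnorm(nrow(tab), 0, 0.1))
  p <- nearest_pairing(tab, tab2, radius = 5)
  res <- feature_correlation(p, "area")
  x <- tab$area
  y <- tab2$area
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$n, nrow(tab))
  # perfect and anti-correlated cases
  tab3 <- tab
  tab3$area <- tab$area
  expect_equal(feature_correlation(nearest_pairing(tab, tab3, 5), "area")$r, 1)
  tab4 <- tab
  tab4$area <- -tab$area
  expect_equal(feature_correlation(nearest_pairing(tab, tab4, 5), "area")$r, -1)
  # zero variance is an error
  tab5 <- tab
  tab5$area <- rep(1, nrow(tab))
  expect_error(feature_correlation(nearest_pairing(tab, tab5, 5), "area"), "variance")
})

test_that("regional density counts preserve totals", {
  # 4 cells inside one bin
  four <- cell_table(rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4)))
  g <- regional_density(four, grid_size = 10, bbox = c(0, 20, 0, 20))
  expect_equal(g[1, 1], 4L)
  expect_equal(sum(g), 4L)
  # empty input -> all-zero grid
  empty <- cell_table(matrix(numeric(0), ncol = 2))
  expect_equal(sum(regional_density(empty, 10, bbox = c(0, 20, 0, 20))), 0L)
  # uniform points split near-multinomially across a 2x2 grid
  set.seed(15)
  xy <- matrix(runif(200, 0, 100), ncol = 2)
  g2 <- regional_density(xy, 50, bbox = c(0, 100, 0, 100))
  expect_equal(sum(g2), 100L)
  expect_true(all(abs(g2 - 25) <= 3 * sqrt(100 * 0.25 * 0.75)))
})

test_that("composition similarity follows 1 - |delta p| with masking", {
  set.seed(16)
  xy <- matrix(runif(400, 0, 100), ncol = 2)
  lab <- rbinom(200, 1, 0.4)
  a <- cell_table(xy, features = data.frame(tumor = lab))
  # identical labeled tables: similarity 1 wherever unmasked
  sim <- composition_similarity(a, a, grid_size = 50, min_cells = 5)
  expect_true(all(sim[!is.na(sim)] == 1))
  # constructed proportions 0.3 vs 0.5 -> similarity 0.8
  sx <- cell_table(cbind(runif(10, 0, 10), runif(10, 0, 10)),
    features = data.frame(tumor = c(rep(1, 3), rep(0, 7)))
  )
  tx <- cell_table(cbind(runif(10, 0, 10), runif(10, 0, 10)),
    features = data.frame(tumor = c(rep(1, 5), rep(0, 5)))
  )
  sim2 <- composition_similarity(sx, tx, grid_size = 10, min_cells = 5,
    bbox = c(0, 10, 0, 10)
  )
  expect_equal(as.numeric(sim2), 0.8, tolerance = 1e-12)
  # everything below min_cells -> fully masked
  sim3 <- composition_similarity(sx, tx, grid_size = 10, min_cells = 50,
    bbox = c(0, 10, 0, 10)
  )
  expect_true(all(is.na(sim3)))
  # missing label column -> configuration error
  b <- cell_table(xy)
  expect_error(composition_similarity(b, b), "label")
})

test_that("feature correlation rises as cross-modal feature noise falls", {
  mean_r <- sapply(c(0.3, 0.1, 0.02), function(noise) {
    rs <- sapply(1:20, function(sd) {
      pair <- generate_core_pair(synthetic_config(
        n_cells = 250, seed = sd, jitter_sd = 0.5, feature_noise_sd = noise
      ))
      aligned <- pair$source
      mapped <- apply_transform(pair$transform, as_xy_matrix(pair$source))
      aligned$x <- mapped[, 1]
      aligned$y <- mapped[, 2]
      feature_correlation(nearest_pairing(aligned, pair$target, 10), "area")$r
    })
    mean(rs)
  })
  expect_true(all(diff(mean_r) > 0))
})

test_that("restained-like simulations outrank serial-like in area concordance", {
  r_of <- function(profile, sd) {
    pair <- generate_core_pair(synthetic_profile(profile, n_cells = 400, seed = sd))
    aligned <- pair$source
    mapped <- apply_transform(pair$transform, as_xy_matrix(pair$source))
    aligned$x <- mapped[, 1]
    aligned$y <- mapped[, 2]
    feature_correlation(nearest_pairing(aligned, pair$target, 10), "area")$r
  }
  wins <- sum(sapply(1:10, function(sd) r_of("restained", sd) > r_of("serial", sd)))
  expect_gte(wins, 9)
})
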
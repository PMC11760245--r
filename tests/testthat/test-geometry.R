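# Transformation model, landmark fitting, alignment metrics.

test_that("homogeneous matrix construction matches hand-computed cases", {
  expect_equal(matrix_from_params(0, 1, 0, 0), diag(3))
  # quarter turn sends (1, 0) to (0, 1)
  p <- apply_transform(rigid_transform(pi / 2, 1, 0, 0), cbind(1, 0))
  expect_equal(as.numeric(p), c(0, 1), tolerance = 1e-12)
  # half turn with scale 2 then shift by (1, 1)
  p2 <- apply_transform(rigid_transform(pi, 2, 1, 1), cbind(1, 0))
  expect_equal(as.numeric(p2), c(-1, 1), tolerance = 1e-12)
  expect_error(matrix_from_params(0, 0, 0, 0), "positive")
  expect_error(rigid_transform(scale = -2), "positive")
})

test_that("params_from_matrix inverts matrix_from_params over random draws", {
  set.seed(11)
  for (i in 1:50) {
    theta <- runif(1, -pi, pi)
    scale <- exp(runif(1, -1, 1))
    dx <- runif(1, -500, 500)
    dy <- runif(1, -500, 500)
    M <- matrix_from_params(theta, scale, dx, dy)
    tf <- params_from_matrix(M)
    expect_equal(transform_matrix(tf), M, tolerance = 1e-9)
    expect_equal(tf$scale, scale, tolerance = 1e-9)
    expect_true(tf$theta > -pi && tf$theta <= pi)
  }
  expect_equal(
    unclass(params_from_matrix(diag(3)))[c("theta", "scale", "dx", "dy")],
    list(theta = 0, scale = 1, dx = 0, dy = 0)
  )
})

test_that("reflections and anisotropic blocks are rejected", {
  refl <- diag(3)
  refl[2, 2] <- -1
  expect_error(params_from_matrix(refl), "similarity")
  aniso <- diag(3)
  aniso[1, 1] <- 2
  expect_error(params_from_matrix(aniso), "similarity")
})

test_that("pixel-to-micron conversion multiplies by the pixel size", {
  expect_equal(
    pixels_to_microns(cbind(100, 200), 0.325),
    cbind(x = 32.5, y = 65.0)
  )
  expect_equal(
    pixels_to_microns(cbind(100, 200), 0.212),
    cbind(x = 21.2, y = 42.4)
  )
  pts <- cbind(runif(5), runif(5))
  expect_equal(unname(pixels_to_microns(pts, 1)), unname(pts))
  expect_error(pixels_to_microns(pts, 0), "positive")
})

test_that("similarity fit recovers generating parameters and is order-invariant", {
  set.seed(7)
  src <- matrix(runif(16, -200, 200), ncol = 2)
  tf <- rigid_transform(0.1, 1, 30, -12)
  tgt <- apply_transform(tf, src)
  fit <- fit_similarity(src, tgt)
  expect_equal(fit$theta, 0.1, tolerance = 1e-9)
  expect_equal(fit$scale, 1, tolerance = 1e-9)
  expect_equal(c(fit$dx, fit$dy), c(30, -12), tolerance = 1e-9)
  expect_lt(attr(fit, "rms_residual"), 1e-9)
  # relabeling the pairs changes nothing
  ord <- sample(nrow(src))
  fit2 <- fit_similarity(src[ord, ], tgt[ord, ])
  expect_equal(unclass(fit2)[1:4], unclass(fit)[1:4], tolerance = 1e-9)
  # identity landmarks give the identity transform
  fit3 <- fit_similarity(src, src)
  expect_equal(fit3$theta, 0, tolerance = 1e-12)
  expect_equal(c(fit3$dx, fit3$dy), c(0, 0), tolerance = 1e-9)
})

test_that("two exact pairs determine the similarity with zero residual", {
  # closed-form 2-point oracle: rotation/scale from the inter-point vector,
  # translation from the first pair
  s <- rbind(c(0, 0), c(10, 5))
  t <- rbind(c(3, -2), c(-4, 9))
  vs <- s[2, ] - s[1, ]
  vt <- t[2, ] - t[1, ]
  scale_o <- sqrt(sum(vt^2) / sum(vs^2))
  theta_o <- atan2(vt[2], vt[1]) - atan2(vs[2], vs[1])
  R <- matrix(c(cos(theta_o), sin(theta_o), -sin(theta_o), cos(theta_o)), 2)
  t_o <- t[1, ] - scale_o * as.numeric(R %*% s[1, ])
  fit <- fit_similarity(s, t)
  expect_equal(fit$scale, scale_o, tolerance = 1e-9)
  expect_equal(sin(fit$theta - theta_o), 0, tolerance = 1e-9)
  expect_equal(c(fit$dx, fit$dy), t_o, tolerance = 1e-9)
  expect_lt(attr(fit, "rms_residual"), 1e-9)
})

test_that("noiseless fits recover parameters for any non-degenerate n >= 2", {
  set.seed(21)
  for (n in c(2, 3, 5, 20)) {
    src <- matrix(runif(2 * n, -100, 100), ncol = 2)
    tf <- rigid_transform(runif(1, -3, 3), exp(runif(1, -0.5, 0.5)),
      runif(1, -50, 50), runif(1, -50, 50)
    )
    fit <- fit_similarity(src, apply_transform(tf, src))
    expect_equal(fit$scale, tf$scale, tolerance = 1e-6)
    expect_equal(sin(fit$theta - tf$theta), 0, tolerance = 1e-6)
  }
  expect_error(fit_similarity(rbind(c(1, 1), c(1, 1)), rbind(c(0, 0), c(2, 2))), "degenerate")
})

test_that("fixed-scale fit clamps S to 1", {
  set.seed(3)
  src <- matrix(runif(12, -50, 50), ncol = 2)
  tgt <- apply_transform(rigid_transform(0.2, 1.5, 5, 5), src)
  fit <- fit_similarity(src, tgt, fix_scale = TRUE)
  expect_identical(fit$scale, 1)
})

test_that("alignment metrics follow their defining identities", {
  set.seed(9)
  src <- matrix(runif(16, -100, 100), ncol = 2)
  gt <- rigid_transform(0.15, 1, 12, -7)
  lms <- landmark_pairs(src, apply_transform(gt, src))
  # estimated == ground truth that maps exactly -> all zeros
  m0 <- evaluate_alignment(gt, gt, lms)
  expect_equal(m0$delta_D, 0, tolerance = 1e-9)
  expect_equal(m0$delta_T, 0, tolerance = 1e-12)
  expect_equal(m0$delta_theta, 0, tolerance = 1e-12)
  # composing with a pure (3, 4) shift gives deltaD = 5 exactly
  shifted <- compose_transforms(rigid_transform(0, 1, 3, 4), gt)
  m1 <- evaluate_alignment(shifted, gt, lms)
  expect_equal(m1$delta_D, 5, tolerance = 1e-9)
  t_gt <- sqrt(gt$dx^2 + gt$dy^2)
  t_sh <- sqrt(shifted$dx^2 + shifted$dy^2)
  expect_equal(m1$delta_T, abs(t_sh - t_gt), tolerance = 1e-9)
  expect_equal(m1$delta_theta, 0, tolerance = 1e-9)
  # an extra 2-degree rotation about the landmark centroid -> deltaTheta = 2
  ctr <- colMeans(lms$target)
  extra <- compose_transforms(
    compose_transforms(
      rigid_transform(0, 1, ctr[1], ctr[2]),
      rigid_transform(2 * pi / 180, 1, 0, 0)
    ),
    rigid_transform(0, 1, -ctr[1], -ctr[2])
  )
  m2 <- evaluate_alignment(compose_transforms(extra, gt), gt, lms)
  expect_equal(m2$delta_theta, 2, tolerance = 1e-9)
})

test_that("deltaD is invariant to landmark reordering and zero iff exact", {
  set.seed(13)
  src <- matrix(runif(16, -100, 100), ncol = 2)
  gt <- rigid_transform(0.3, 1, -5, 8)
  tgt <- apply_transform(gt, src)
  est <- rigid_transform(0.31, 1, -5, 8)
  ord <- sample(8)
  m_a <- evaluate_alignment(est, gt, landmark_pairs(src, tgt))
  m_b <- evaluate_alignment(est, gt, landmark_pairs(src[ord, ], tgt[ord, ]))
  expect_equal(m_a$delta_D, m_b$delta_D, tolerance = 1e-12)
  expect_gt(m_a$delta_D, 0)
})

test_that("compose and invert are consistent", {
  a <- rigid_transform(0.4, 1.2, 3, -6)
  b <- rigid_transform(-0.9, 0.8, -11, 2)
  ab <- compose_transforms(a, b)
  p <- cbind(runif(4), runif(4))
  expect_equal(apply_transform(ab, p), apply_transform(a, apply_transform(b, p)),
    tolerance = 1e-9
  )
  ida <- compose_transforms(a, invert_transform(a))
  expect_equal(transform_matrix(ida), diag(3), tolerance = 1e-9)
})
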
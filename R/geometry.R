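# Transformation model, landmark fitting and alignment metrics.
#
# All geometry works in micrometers. The coordinate frame follows the image
# convention of the upstream segmentation exports: origin top-left, x to the
# right, y downward; theta is measured counter-clockwise in that frame.

#' Planar similarity (rigid + scale) transform
#'
#' The transform maps a point \eqn{(x, y)} to
#' \deqn{(S\cos\theta\, x - S\sin\theta\, y + dx,\; S\sin\theta\, x + S\cos\theta\, y + dy)}
#' i.e. rotation by `theta`, isotropic scaling by `scale`, then translation by
#' `(dx, dy)`. When both modalities have been converted to micrometers the
#' scale between them is 1 and the transform is rigid; the scale parameter is
#' retained for landmark-derived ground-truth fits where it is estimated
#' freely.
#'
#' @param theta Rotation angle in radians, counter-clockwise.
#' @param scale Isotropic scale factor, must be strictly positive.
#' @param dx,dy Translation in micrometers.
#' @return An object of class `rigid_transform`.
#' @seealso [transform_matrix()], [params_from_matrix()], [fit_similarity()]
#' @export
#' @examples
#' tf <- rigid_transform(theta = pi / 2, scale = 1, dx = 0, dy = 0)
#' apply_transform(tf, cbind(1, 0)) # rotates (1, 0) onto (0, 1)
rigid_transform <- function(theta = 0, scale = 1, dx = 0, dy = 0) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive finite number", call. = FALSE)
  }
  vals <- c(theta = theta, dx = dx, dy = dy)
  if (!all(is.finite(vals))) {
    stop("transform parameters must be finite", call. = FALSE)
  }
  structure(
    list(
      theta = as.numeric(unname(wrap_angle(theta))), scale = as.numeric(unname(scale)),
      dx = as.numeric(unname(dx)), dy = as.numeric(unname(dy))
    ),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> theta = %.6g rad (%.4g deg), scale = %.6g, t = (%.6g, %.6g) um\n",
    x$theta, rad2deg(x$theta), x$scale, x$dx, x$dy
  ))
  rms <- attr(x, "rms_residual")
  if (!is.null(rms)) cat(sprintf("  landmark fit residual RMS: %.4g um\n", rms))
  invisible(x)
}

# Wrap an angle to (-pi, pi].
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Homogeneous 3x3 matrix of a similarity transform
#'
#' @param theta,scale,dx,dy Transform parameters as in [rigid_transform()];
#'   alternatively pass a `rigid_transform` as the first argument.
#' @return A 3x3 numeric matrix `M` such that `M %*% c(x, y, 1)` applies the
#'   transform.
#' @export
matrix_from_params <- function(theta, scale = 1, dx = 0, dy = 0) {
  if (inherits(theta, "rigid_transform")) {
    tf <- theta
    theta <- tf$theta; scale <- tf$scale; dx <- tf$dx; dy <- tf$dy
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive finite number", call. = FALSE)
  }
  rbind(
    c(scale * cos(theta), -scale * sin(theta), dx),
    c(scale * sin(theta), scale * cos(theta), dy),
    c(0, 0, 1)
  )
}

#' @rdname matrix_from_params
#' @param tf A `rigid_transform`.
#' @export
transform_matrix <- function(tf) matrix_from_params(tf)

#' Recover similarity parameters from a homogeneous matrix
#'
#' The inverse of [matrix_from_params()]. The upper-left 2x2 block must be a
#' positively scaled rotation: reflections (negative determinant) and
#' anisotropic or shearing blocks are rejected, since neither arises from the
#' supported transformation model.
#'
#' @param M A 3x3 homogeneous matrix.
#' @param tol Relative tolerance for the similarity check.
#' @return A `rigid_transform`; `theta` lies in `(-pi, pi]`.
#' @export
params_from_matrix <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(3L, 3L))) stop("`M` must be a 3x3 matrix", call. = FALSE)
  if (max(abs(M[3, ] - c(0, 0, 1))) > tol) {
    stop("`M` is not an affine homogeneous matrix (last row must be 0 0 1)", call. = FALSE)
  }
  A <- M[1:2, 1:2]
  d <- det(A)
  if (d <= 0) {
    stop("not a similarity transform: reflection or singular 2x2 block", call. = FALSE)
  }
  # For A = s R, t(A) %*% A == s^2 I; anything else is anisotropic/shear.
  gram <- crossprod(A)
  if (max(abs(gram - d * diag(2))) > tol * max(1, d)) {
    stop("not a similarity transform: anisotropic or shearing 2x2 block", call. = FALSE)
  }
  rigid_transform(
    theta = atan2(A[2, 1], A[1, 1]),
    scale = sqrt(d),
    dx = M[1, 3],
    dy = M[2, 3]
  )
}

#' Apply a similarity transform to points
#'
#' @param tf A `rigid_transform` or 3x3 homogeneous matrix.
#' @param xy An n x 2 coordinate matrix (or cell table / data frame with
#'   columns `x`, `y`), in micrometers.
#' @return An n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(tf, xy) {
  M <- if (inherits(tf, "rigid_transform")) transform_matrix(tf) else as.matrix(tf)
  p <- as_xy(xy)
  out <- p %*% t(M[1:2, 1:2])
  out[, 1] <- out[, 1] + M[1, 3]
  out[, 2] <- out[, 2] + M[2, 3]
  colnames(out) <- c("x", "y")
  out
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `inner` first, then `outer`.
#'
#' @param outer,inner `rigid_transform` objects.
#' @export
compose_transforms <- function(outer, inner) {
  params_from_matrix(transform_matrix(outer) %*% transform_matrix(inner))
}

#' Invert a similarity transform
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  params_from_matrix(solve(transform_matrix(tf)))
}

#' Convert pixel coordinates to micrometers
#'
#' Multiplies every coordinate by the pixel size. Converting both modalities
#' to micrometers before registration removes the scale degree of freedom, so
#' the point-set alignment can run with the scale fixed at 1.
#'
#' @param xy An n x 2 coordinate matrix in pixels.
#' @param pixel_size Pixel size in micrometers per pixel (e.g. 0.325 for a
#'   typical MxIF scan, 0.212 for H&E).
#' @return An n x 2 matrix in micrometers.
#' @export
pixels_to_microns <- function(xy, pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  }
  as_xy(xy) * pixel_size
}

#' Index-paired landmark annotations in both modalities
#'
#' Landmarks are manually annotated corresponding points (typically cell
#' centers near distinctive microarchitecture) used to derive a ground-truth
#' transform and to score automatic alignments. Two non-coincident pairs
#' already determine the 4-parameter similarity; eight pairs per core is a
#' practical annotation workload.
#'
#' @param source,target n x 2 coordinate matrices (micrometers), index-paired.
#' @return An object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(source, target) {
  s <- as_xy(source)
  t <- as_xy(target)
  if (nrow(s) != nrow(t)) stop("source and target landmark counts differ", call. = FALSE)
  if (nrow(s) < 2L) stop("at least 2 landmark pairs are required", call. = FALSE)
  if (!all(is.finite(s)) || !all(is.finite(t))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  if (anyDuplicated(s)) stop("duplicate source landmarks", call. = FALSE)
  structure(list(source = s, target = t), class = "landmark_pairs")
}

#' @export
print.landmark_pairs <- function(x, ...) {
  cat(sprintf("<landmark_pairs> %d pairs\n", nrow(x$source)))
  invisible(x)
}

#' Least-squares similarity transform between paired point sets
#'
#' Procrustes/Umeyama estimate of the similarity transform minimizing
#' \eqn{\sum_i \| t_i - M s_i \|^2} over rotation, translation and
#' (optionally) isotropic scale. The rotation comes from the SVD of the
#' cross-covariance with a determinant correction that excludes reflections.
#'
#' With `fix_scale = TRUE` the scale is clamped to 1 and only rotation and
#' translation are estimated -- the operating mode of the registration
#' pipeline once both modalities are in micrometers. Ground-truth fits from
#' landmarks leave the scale free.
#'
#' @param source A `landmark_pairs` object, or an n x 2 source matrix.
#' @param target Target n x 2 matrix (ignored when `source` is a
#'   `landmark_pairs`).
#' @param fix_scale Clamp the scale to 1?
#' @return A `rigid_transform` mapping source onto target, with attribute
#'   `rms_residual` (root-mean-square landmark residual, um).
#' @export
fit_similarity <- function(source, target = NULL, fix_scale = FALSE) {
  if (inherits(source, "landmark_pairs")) {
    target <- source$target
    source <- source$source
  }
  s <- as_xy(source)
  t <- as_xy(target)
  if (nrow(s) != nrow(t)) stop("paired point sets differ in length", call. = FALSE)
  if (nrow(s) < 2L) stop("at least 2 point pairs are required", call. = FALSE)
  mu_s <- colMeans(s)
  mu_t <- colMeans(t)
  sc <- sweep(s, 2, mu_s)
  tc <- sweep(t, 2, mu_t)
  var_s <- sum(sc^2)
  if (var_s < .Machine$double.eps) {
    stop("degenerate configuration: all source points coincident", call. = FALSE)
  }
  # H = sum_i sc_i tc_i^T ; rotation maximizes tr(R H)
  H <- crossprod(sc, tc)
  sv <- svd(H)
  C <- diag(c(1, sign(det(sv$u) * det(sv$v))))
  R <- sv$v %*% C %*% t(sv$u)
  scale <- if (fix_scale) 1 else sum(diag(C) * sv$d) / var_s
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate configuration: could not estimate a positive scale", call. = FALSE)
  }
  tr <- mu_t - scale * as.numeric(R %*% mu_s)
  tf <- rigid_transform(
    theta = atan2(R[2, 1], R[1, 1]),
    scale = scale,
    dx = tr[1],
    dy = tr[2]
  )
  resid <- t - apply_transform(tf, s)
  attr(tf, "rms_residual") <- sqrt(mean(rowSums(resid^2)))
  tf
}

#' Landmark-based alignment accuracy metrics
#'
#' Scores an estimated transform against a landmark-derived ground truth with
#' three complementary errors:
#' \describe{
#'   \item{`delta_D`}{mean Euclidean distance (um) between each target
#'     landmark and the corresponding source landmark mapped through the
#'     *estimated* transform -- the overall alignment error;}
#'   \item{`delta_T`}{absolute difference of translation magnitudes
#'     \eqn{|T' - T|} with \eqn{T = \sqrt{dx^2 + dy^2}} (um);}
#'   \item{`delta_theta`}{absolute rotation difference in degrees, wrapped to
#'     `[0, 180]`.}
#' }
#'
#' @param estimated,ground_truth `rigid_transform` objects.
#' @param landmarks A `landmark_pairs` object.
#' @return An object of class `alignment_metrics`: a list with fields
#'   `delta_D`, `delta_T`, `delta_theta`.
#' @export
evaluate_alignment <- function(estimated, ground_truth, landmarks) {
  if (!inherits(landmarks, "landmark_pairs")) {
    stop("`landmarks` must be a landmark_pairs object", call. = FALSE)
  }
  if (nrow(landmarks$source) < 1L) stop("landmarks must be non-empty", call. = FALSE)
  mapped <- apply_transform(estimated, landmarks$source)
  delta_D <- mean(sqrt(rowSums((landmarks$target - mapped)^2)))
  T_est <- sqrt(estimated$dx^2 + estimated$dy^2)
  T_gt <- sqrt(ground_truth$dx^2 + ground_truth$dy^2)
  delta_theta <- abs(rad2deg(wrap_angle(estimated$theta - ground_truth$theta)))
  structure(
    list(delta_D = delta_D, delta_T = abs(T_est - T_gt), delta_theta = delta_theta),
    class = "alignment_metrics"
  )
}

#' @export
print.alignment_metrics <- function(x, ...) {
  cat(sprintf(
    "<alignment_metrics> deltaD = %.4g um, deltaT = %.4g um, deltaTheta = %.4g deg\n",
    x$delta_D, x$delta_T, x$delta_theta
  ))
  invisible(x)
}
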
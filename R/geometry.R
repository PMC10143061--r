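#' Camera intrinsic parameters
#'
#' Container for the intrinsic parameters of the microscope camera: the
#' focal scales `fx`, `fy` (pixel per micrometre on the stage plane), the
#' principal point `(u0, v0)` (pixel, 0-based, u = column, v = row, origin
#' at the top-left pixel centre) and the second-order radial distortion
#' factor `k` (pixel^-2).  Radial distortion displaces an observed point
#' radially about the principal point by `k * offset * r^2`.
#'
#' @param fx,fy Focal scales along u and v (pixel/µm), strictly positive.
#' @param u0,v0 Principal point (pixel).
#' @param k Second-order radial distortion factor (pixel^-2).
#' @param image_size Optional `c(width, height)` in pixels; when given, a
#'   principal point outside the frame is flagged (attribute
#'   `extrapolated`), not rejected.
#' @return An object of class `intrinsic_params`.
#' @examples
#' intrinsic_params(1, 1, 600, 450, 5e-8)
#' @export
intrinsic_params <- function(fx = 1, fy = 1, u0 = 0, v0 = 0, k = 0,
                             image_size = NULL) {
  vals <- c(fx = fx, fy = fy, u0 = u0, v0 = v0, k = k)
  if (!all(is.finite(vals)))
    stop("intrinsic parameters must all be finite")
  if (fx <= 0 || fy <= 0)
    stop("focal scales fx, fy must be positive")
  out <- structure(list(fx = fx, fy = fy, u0 = u0, v0 = v0, k = k),
                   class = "intrinsic_params")
  if (!is.null(image_size)) {
    attr(out, "extrapolated") <-
      u0 < 0 || u0 > image_size[1] - 1 || v0 < 0 || v0 > image_size[2] - 1
  }
  out
}

#' @export
print.intrinsic_params <- function(x, ...) {
  cat("Camera intrinsics\n")
  cat(sprintf("  fx = %.6g px/um, fy = %.6g px/um\n", x$fx, x$fy))
  cat(sprintf("  principal point (u0, v0) = (%.3f, %.3f) px\n", x$u0, x$v0))
  cat(sprintf("  radial distortion k = %.6g px^-2\n", x$k))
  invisible(x)
}

#' Intrinsic parameter matrix A
#'
#' The 3x3 upper-triangular intrinsic matrix with zero skew.
#' @param intr An [intrinsic_params()] object.
#' @return 3x3 numeric matrix.
#' @export
intrinsic_matrix <- function(intr) {
  matrix(c(intr$fx, 0, intr$u0,
           0, intr$fy, intr$v0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

.as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2)
    p
  } else {
    stopifnot(length(p) == 2)
    matrix(p, ncol = 2)
  }
}

#' Map observed (distorted) image points to theoretical points
#'
#' Applies the second-order radial distortion correction: an observed point
#' `(u, v)` maps to `(u + k (u - u0) r^2, v + k (v - v0) r^2)` with
#' `r^2 = (u - u0)^2 + (v - v0)^2`.  The correction vanishes at the
#' principal point and when `k = 0`.
#'
#' @param p A length-2 vector `c(u, v)` or an n x 2 matrix of points (pixel).
#' @param intr An [intrinsic_params()] object.
#' @return Points of the same shape as `p`, in theoretical (undistorted)
#'   image coordinates.
#' @seealso [distort_point()] for the numerical inverse.
#' @examples
#' undistort_point(c(610, 450), intrinsic_params(u0 = 600, v0 = 450, k = 1e-6))
#' @export
undistort_point <- function(p, intr) {
  was_vec <- !is.matrix(p)
  pm <- .as_point_matrix(p)
  if (!all(is.finite(pm))) stop("points must be finite")
  du <- pm[, 1] - intr$u0
  dv <- pm[, 2] - intr$v0
  r2 <- du * du + dv * dv
  out <- cbind(pm[, 1] + intr$k * du * r2,
               pm[, 2] + intr$k * dv * r2)
  if (was_vec) drop(out) else out
}

#' Map theoretical image points to observed (distorted) points
#'
#' Numerical inverse of [undistort_point()].  The forward correction is
#' cubic in the radial offset, so the inverse is found by damped Newton
#' iteration on the radial magnitude, starting from the theoretical point.
#' Convergence tolerance is 1e-12 px^2 on the squared update; at most 50
#' iterations are attempted.
#'
#' @inheritParams undistort_point
#' @param p Theoretical image point(s); must lie within the monotone radius
#'   of the distortion map (`|3 k r^2| < 1`).
#' @return Observed image points, same shape as `p`.
#' @export
distort_point <- function(p, intr) {
  was_vec <- !is.matrix(p)
  pm <- .as_point_matrix(p)
  if (!all(is.finite(pm))) stop("points must be finite")
  k <- intr$k
  du <- pm[, 1] - intr$u0
  dv <- pm[, 2] - intr$v0
  if (k == 0) return(if (was_vec) drop(pm) else pm)
  # radial: theoretical radius s = r + k r^3; solve r given s by Newton
  s <- sqrt(du * du + dv * dv)
  r <- s
  ok <- rep(FALSE, length(s))
  for (it in seq_len(50L)) {
    f <- r + k * r^3 - s
    fp <- 1 + 3 * k * r^2
    if (any(fp <= 0)) stop("point outside the monotone radius of the distortion map")
    step <- f / fp
    r <- r - step
    ok <- abs(step)^2 < 1e-12
    if (all(ok)) break
  }
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("distortion inversion did not converge for point (%.6g, %.6g)",
                 pm[bad, 1], pm[bad, 2]))
  }
  scale <- ifelse(s > 0, r / s, 1)
  out <- cbind(intr$u0 + du * scale, intr$v0 + dv * scale)
  if (was_vec) drop(out) else out
}

#' Normalized homography
#'
#' Wraps a 3x3 projective map between the stage plane and the image plane.
#' The matrix is scale-free; the stored representative is normalized to unit
#' Frobenius norm with its largest-magnitude entry positive.
#'
#' @param H A 3x3 numeric matrix of full rank.
#' @return An object of class `homography` (a normalized 3x3 matrix).
#' @export
homography <- function(H) {
  H <- as.matrix(H)
  stopifnot(all(dim(H) == c(3, 3)), all(is.finite(H)))
  if (qr(H)$rank < 3) stop("homography matrix must have rank 3")
  H <- H / sqrt(sum(H^2))
  if (H[which.max(abs(H))] < 0) H <- -H
  structure(H, class = c("homography", "matrix"))
}

#' @export
print.homography <- function(x, ...) {
  cat("Homography (unit Frobenius norm):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Per-axis signed mechanical displacement errors
#'
#' Relative (dimensionless) displacement errors of the stage screws for the
#' four motion directions +X, -X, +Y, -Y.  A relative error of -0.01 means
#' the stage travels 1% short of the commanded distance in that direction.
#' The raw mean pixel offsets per step and the nominal step used during
#' estimation are retained for traceability.
#'
#' @param dxp,dxm,dyp,dym Relative errors for +X, -X, +Y, -Y motion.
#' @param raw_px Optional named numeric of underlying mean pixel offset
#'   errors per step (same order).
#' @param step_um Nominal step length used during estimation (µm).
#' @param px_per_um Pixel scale used to convert offsets (pixel/µm).
#' @return An object of class `axis_errors`.
#' @export
axis_errors <- function(dxp = 0, dxm = 0, dyp = 0, dym = 0,
                        raw_px = NULL, step_um = NA_real_,
                        px_per_um = NA_real_) {
  d <- c(dxp = dxp, dxm = dxm, dyp = dyp, dym = dym)
  if (!all(is.finite(d))) stop("axis errors must be finite")
  if (any(abs(d) >= 0.1))
    stop("relative displacement errors with |error| >= 0.1 are implausible for a functioning stage")
  structure(list(dxp = dxp, dxm = dxm, dyp = dyp, dym = dym,
                 raw_px = raw_px, step_um = step_um, px_per_um = px_per_um),
            class = "axis_errors")
}

#' @export
print.axis_errors <- function(x, ...) {
  cat("Per-axis relative displacement errors:\n")
  cat(sprintf("  +X: %+.5f   -X: %+.5f\n  +Y: %+.5f   -Y: %+.5f\n",
              x$dxp, x$dxm, x$dyp, x$dym))
  if (!is.null(x$raw_px))
    cat(sprintf("  (raw mean offsets %s px at %.5g um steps)\n",
                paste(sprintf("%.2f", unlist(x$raw_px)), collapse = "/"),
                x$step_um))
  invisible(x)
}

#' Camera deflection parameters
#'
#' The mounting deflection angle `theta` between image and stage axes, and
#' the first-order conversion factors `eps_x`, `eps_y` used by the error
#' transform.  By default the factors follow the small-angle rotation
#' convention `eps_x = -eps_y = sin(theta)`; both are exposed separately so
#' that a non-orthogonality term can be injected.
#'
#' @param theta_deg Deflection angle (degrees), `|theta| < 45`.
#' @param eps_x,eps_y Optional explicit conversion factors (dimensionless).
#' @return An object of class `deflection_params`.
#' @export
deflection_params <- function(theta_deg = 0, eps_x = NULL, eps_y = NULL) {
  stopifnot(is.finite(theta_deg))
  if (abs(theta_deg) >= 45)
    stop("|theta| must be below 45 degrees")
  s <- sin(theta_deg * pi / 180)
  if (is.null(eps_x)) eps_x <- s
  if (is.null(eps_y)) eps_y <- -s
  stopifnot(is.finite(eps_x), is.finite(eps_y))
  structure(list(theta_deg = theta_deg, eps_x = eps_x, eps_y = eps_y),
            class = "deflection_params")
}

#' Extrinsic pose of the stage plane
#'
#' @param R 3x3 rotation matrix (orthonormal within 1e-9, det +1).
#' @param t Translation 3-vector (µm).
#' @param t_hat Corrected translation 3-vector (µm), defaulting to `t`.
#' @return An object of class `extrinsic_pose`.
#' @export
extrinsic_pose <- function(R = diag(3), t = c(0, 0, 0), t_hat = t) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3, length(t_hat) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("R must be orthonormal (R'R = I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("R must be a proper rotation (det = +1)")
  structure(list(R = R, t = as.numeric(t), t_hat = as.numeric(t_hat)),
            class = "extrinsic_pose")
}

#' Assemble the combined error transformation matrix
#'
#' Builds the 3x3 homogeneous error transform
#' `T = M' * [1 eps_y dx; eps_x 1 dy; 0 0 1] * [R2 t_hat2; 0 0 1]`,
#' the product of the magnification/distortion factor, the mounting
#' deflection block with the per-axis displacement offsets in the third
#' column, and the planar part of the extrinsic pose (upper-left 2x2 of `R`
#' with the first two components of `t_hat`).
#'
#' With `M' = 1`, zero deflection factors, zero displacement errors,
#' `R = I` and `t_hat = 0` the transform is the identity.
#'
#' @param M_prime Magnification ratio (actual / nominal), positive scalar.
#' @param deflection A [deflection_params()] object.
#' @param axis An [axis_errors()] object; the +X / +Y errors fill the
#'   offset slots (`dx = dxp`, `dy = dyp`); use [mu()] for direction-aware
#'   selection.
#' @param pose An [extrinsic_pose()] object.
#' @return 3x3 numeric matrix of class `error_transform`.
#' @export
compose_error_transform <- function(M_prime = 1,
                                    deflection = deflection_params(),
                                    axis = axis_errors(),
                                    pose = extrinsic_pose()) {
  stopifnot(is.finite(M_prime), M_prime > 0)
  E <- matrix(c(1, deflection$eps_y, axis$dxp,
                deflection$eps_x, 1, axis$dyp,
                0, 0, 1), 3, 3, byrow = TRUE)
  P <- rbind(cbind(pose$R[1:2, 1:2], pose$t_hat[1:2]), c(0, 0, 1))
  structure(M_prime * E %*% P, class = c("error_transform", "matrix"))
}
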
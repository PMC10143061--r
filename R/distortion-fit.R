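# Plumb-line distortion calibration: straight world lines must image to
# straight lines after the radial correction.  The objective is the sum of
# squared point-to-line distances of the corrected centerline samples,
# minimized jointly over the distortion parameters (k, u0, v0) and the
# per-line Hessian-form parameters (alpha_i, phi_i).

.collect_lines <- function(lines) {
  if (inherits(lines, "center_line_set")) c(lines$vertical, lines$horizontal)
  else lines
}

#' Straightness residuals of corrected centerline points
#'
#' For line i with parameters `(alpha_i, phi_i)` and sample j at
#' `(u_ij, v_ij)`, the residual is
#' `u_hat cos(alpha_i) + v_hat sin(alpha_i) + phi_i`, where
#' `(u_hat, v_hat)` is the radially corrected point about `(u0, v0)` with
#' factor `k`.  The calibration objective is the sum of squared residuals.
#'
#' @param k,u0,v0 Distortion parameters.
#' @param alpha,phi Per-line tilt (radians) and intercept (pixel), one per
#'   line in `lines`.
#' @param lines A `center_line_set` or list of `center_line` objects.
#' @return Numeric vector of residuals (pixel), points of line 1 first.
#' @export
straightness_residuals <- function(k, u0, v0, alpha, phi, lines) {
  ll <- .collect_lines(lines)
  stopifnot(length(alpha) == length(ll), length(phi) == length(ll))
  unlist(lapply(seq_along(ll), function(i) {
    p <- ll[[i]]$points
    du <- p[, 1] - u0; dv <- p[, 2] - v0
    r2 <- du * du + dv * dv
    (p[, 1] + k * du * r2) * cos(alpha[i]) +
      (p[, 2] + k * dv * r2) * sin(alpha[i]) + phi[i]
  }), use.names = FALSE)
}

# residuals and analytic Jacobian for the stacked parameter vector
# par = (k, u0, v0, alpha_1..n, phi_1..n)
.straightness_fn <- function(par, pts, idx, nlines) {
  k <- par[1]; u0 <- par[2]; v0 <- par[3]
  alpha <- par[3 + seq_len(nlines)]
  phi <- par[3 + nlines + seq_len(nlines)]
  du <- pts[, 1] - u0; dv <- pts[, 2] - v0
  r2 <- du * du + dv * dv
  ca <- cos(alpha)[idx]; sa <- sin(alpha)[idx]
  (pts[, 1] + k * du * r2) * ca + (pts[, 2] + k * dv * r2) * sa + phi[idx]
}

.straightness_jac <- function(par, pts, idx, nlines) {
  k <- par[1]; u0 <- par[2]; v0 <- par[3]
  alpha <- par[3 + seq_len(nlines)]
  du <- pts[, 1] - u0; dv <- pts[, 2] - v0
  r2 <- du * du + dv * dv
  ca <- cos(alpha)[idx]; sa <- sin(alpha)[idx]
  uh <- pts[, 1] + k * du * r2
  vh <- pts[, 2] + k * dv * r2
  n <- nrow(pts)
  J <- matrix(0, n, 3 + 2 * nlines)
  J[, 1] <- du * r2 * ca + dv * r2 * sa
  J[, 2] <- -k * ((r2 + 2 * du * du) * ca + 2 * dv * du * sa)
  J[, 3] <- -k * (2 * du * dv * ca + (r2 + 2 * dv * dv) * sa)
  dalpha <- -uh * sa + vh * ca
  J[cbind(seq_len(n), 3 + idx)] <- dalpha
  J[cbind(seq_len(n), 3 + nlines + idx)] <- 1
  J
}

#' Fit the radial distortion model by line straightness
#'
#' Minimizes the plumb-line objective (sum of squared point-to-line
#' distances of the radially corrected centerline samples) over
#' `(k, u0, v0)` and all per-line `(alpha_i, phi_i)` using
#' Levenberg-Marquardt with an analytic Jacobian.  Per-line parameters are
#' initialized by total-least-squares fits to the raw points; `(u0, v0)`
#' starts at the raster centre and `k` at zero unless `init` overrides.
#'
#' @param lines A `center_line_set` (both families required, at least 4
#'   lines in total) or list of `center_line` objects.
#' @param init Optional named list/vector with any of `k`, `u0`, `v0`.
#' @param image_size `c(w, h)`; defaults to the attribute carried by the
#'   `center_line_set`.
#' @param subsample Keep every `subsample`-th point of each line (speed).
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `distortion_fit`: list with `intr`
#'   ([intrinsic_params()] holding the fitted `k, u0, v0`; focal scales
#'   are set to 1 until resolved by the homography step), `alpha`, `phi`,
#'   `lines`, `objective_value` (px^2), `converged`, `n_iterations`, and
#'   `rss_trace` (objective after each accepted LM step).
#' @export
fit_distortion <- function(lines, init = NULL, image_size = NULL,
                           subsample = 2L, control = NULL) {
  ll <- .collect_lines(lines)
  if (length(ll) < 4)
    stop("need at least 4 centerlines to fit the distortion model")
  orient <- vapply(ll, function(l) l$orientation, "")
  if (inherits(lines, "center_line_set") &&
      (!any(orient == "vertical") || !any(orient == "horizontal")))
    stop("degenerate geometry: both line families are required")
  if (is.null(image_size)) image_size <- attr(lines, "image_size")
  if (is.null(image_size))
    stop("image_size must be given when `lines` carries no image-size attribute")
  nlines <- length(ll)
  keep <- lapply(ll, function(l) {
    n <- l$m
    l$points[seq(1L, n, by = max(1L, as.integer(subsample))), , drop = FALSE]
  })
  pts <- do.call(rbind, keep)
  idx <- rep(seq_len(nlines), vapply(keep, nrow, 0L))
  if (nrow(pts) < 3 + 2 * nlines)
    stop("not enough centerline points (", nrow(pts), ") for ",
         3 + 2 * nlines, " parameters")
  tls <- lapply(ll, function(l) .tls_line(l$points))
  par <- c(k = 0, u0 = (image_size[1] - 1) / 2, v0 = (image_size[2] - 1) / 2,
           vapply(tls, `[[`, 0, "alpha"), vapply(tls, `[[`, 0, "phi"))
  for (nm in intersect(names(init), c("k", "u0", "v0")))
    par[nm] <- init[[nm]]
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  c(list(maxiter = 200), control))
  res <- minpack.lm::nls.lm(par = par, fn = .straightness_fn,
                            jac = .straightness_jac,
                            pts = pts, idx = idx, nlines = nlines,
                            control = ctrl)
  if (res$info %in% c(0L, 5L))
    warning("Levenberg-Marquardt did not converge: ", res$message)
  p <- res$par
  intr <- intrinsic_params(fx = 1, fy = 1, u0 = p[["u0"]], v0 = p[["v0"]],
                           k = p[["k"]], image_size = image_size)
  structure(list(intr = intr,
                 alpha = unname(p[3 + seq_len(nlines)]),
                 phi = unname(p[3 + nlines + seq_len(nlines)]),
                 orientation = orient,
                 lines = lines,
                 objective_value = sum(res$fvec^2),
                 converged = res$info %in% 1:4,
                 n_iterations = res$niter,
                 rss_trace = res$rsstrace,
                 image_size = image_size),
            class = "distortion_fit")
}

#' @export
print.distortion_fit <- function(x, ...) {
  cat("Plumb-line distortion fit\n")
  cat(sprintf("  k  = %.6g px^-2\n", x$intr$k))
  cat(sprintf("  (u0, v0) = (%.3f, %.3f) px\n", x$intr$u0, x$intr$v0))
  cat(sprintf("  %d lines, objective %.4g px^2, %s after %d iterations\n",
              length(x$alpha), x$objective_value,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}
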
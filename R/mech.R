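# Per-axis mechanical displacement error estimation from stepped image
# series, and the direction-dependent (quadrant) compensation coefficient.

#' Axis error from measured per-step pixel offsets
#'
#' Pure arithmetic core: the mean per-step pixel offset error and its
#' relative (dimensionless) form `mean / (step_um * px_per_um)`.  Offsets
#' follow the convention that an undershooting stage gives a negative
#' error in every direction (the measured travel magnitude falls short of
#' the commanded magnitude).
#'
#' @param err_px Per-pair signed offset errors (pixel).
#' @param step_um Nominal step (µm).
#' @param px_per_um Pixel scale (px/µm).
#' @return List with `raw_px` (mean pixel error), `delta_rel` (relative
#'   error) and `per_pair_px`.
#' @export
axis_error_from_offsets <- function(err_px, step_um, px_per_um) {
  stopifnot(length(err_px) >= 1, all(is.finite(err_px)),
            step_um > 0, px_per_um > 0)
  m <- mean(err_px)
  list(raw_px = m, delta_rel = m / (step_um * px_per_um),
       per_pair_px = err_px)
}

#' Estimate one direction's mechanical displacement error from a series
#'
#' Registers each consecutive pair of a stepped series, rotates the
#' measured offsets back by the (already calibrated) deflection angle so
#' they are expressed in stage axes, and compares the along-axis travel
#' against the nominal step.  The relative error is the mean pixel error
#' divided by the nominal step in pixels; it is signed so that an
#' undershooting stage yields a negative value for both the positive and
#' the negative motion direction.
#'
#' @param frames List of rasters from a single-direction series.
#' @param plan The [displacement_plan()] of the series.
#' @param px_per_um Calibrated pixel scale (px/µm).
#' @param theta_deg Calibrated deflection angle (degrees) to compensate.
#' @param intr Optional [intrinsic_params()] for corner undistortion.
#' @param search Search half-width around the nominal offset (px).
#' @return List with `delta_rel`, `raw_px`, `per_pair_px`, `axis`,
#'   `direction`, `step_um`, `px_per_um`.
#' @export
axis_error_from_series <- function(frames, plan, px_per_um,
                                   theta_deg = 0, intr = NULL, search = 40,
                                   corners = NULL) {
  stopifnot(length(frames) >= 2, px_per_um > 0)
  a <- -theta_deg * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  step_px <- plan$step_um * px_per_um
  init_stage <- if (plan$axis == "x") c(plan$direction * step_px, 0)
                else c(0, plan$direction * step_px)
  init <- solve(rot, init_stage)  # nominal offset in image axes
  if (is.null(corners))
    corners <- lapply(frames, function(f)
      tryCatch(.grid_corners(f, intr), error = function(e) NULL))
  n <- length(frames) - 1L
  err <- numeric(n)
  for (i in seq_len(n)) {
    o <- tryCatch(
      estimate_offset(frames[[i]], frames[[i + 1]], init = init,
                      search = search, intr = intr,
                      cornersA = corners[[i]], cornersB = corners[[i + 1]]),
      error = function(e)
        stop("registration failed on pair ", i, "/", i + 1, ": ",
             conditionMessage(e)))
    stage_off <- rot %*% c(o$dx, o$dy)
    along <- if (plan$axis == "x") stage_off[1] else stage_off[2]
    err[i] <- plan$direction * along - step_px
  }
  res <- axis_error_from_offsets(err, plan$step_um, px_per_um)
  c(res, list(axis = plan$axis, direction = plan$direction,
              step_um = plan$step_um, px_per_um = px_per_um))
}

.quadrant <- function(beta) {
  b <- beta %% 360
  if (b < 90) 1L else if (b < 180) 2L else if (b < 270) 3L else 4L
}

#' Direction-dependent mechanical error compensation coefficient
#'
#' Selects the `(delta_x, delta_y)` pair by the motion direction's
#' quadrant (half-open: \[0, 90) is the first quadrant, etc.; 90° falls in
#' the second).  In `per_axis` mode (the default used for compensation)
#' the result is the pair of axis gains `(1 + delta_x_sel,
#' 1 + delta_y_sel)`, which reduces to `(1, 1)` when no error was
#' measured.  In `scalar` mode the printed single-coefficient form is
#' evaluated literally with the magnitudes of cos and sin:
#' `(1 + delta_x_sel) |cos(beta)| + (1 + delta_y_sel) |sin(beta)|` —
#' retained for auditability although it equals `sqrt(2)`, not 1, for an
#' error-free stage at 45°.
#'
#' @param beta Direction angle in degrees measured from +X, in
#'   \[0, 360).
#' @param axis An [axis_errors()] object.
#' @param mode `"per_axis"` or `"scalar"`.
#' @return `c(mu_x, mu_y)` in per-axis mode, a scalar otherwise.
#' @export
mu <- function(beta, axis, mode = c("per_axis", "scalar")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(beta), inherits(axis, "axis_errors"))
  q <- .quadrant(beta)
  dx <- if (q %in% c(1L, 4L)) axis$dxp else axis$dxm
  dy <- if (q %in% c(1L, 2L)) axis$dyp else axis$dym
  if (mode == "per_axis") c(mu_x = 1 + dx, mu_y = 1 + dy)
  else (1 + dx) * abs(cospi(beta / 180)) + (1 + dy) * abs(sinpi(beta / 180))
}
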
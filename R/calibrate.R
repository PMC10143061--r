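#' Calibrate a microscope stage from grid images and displacement series
#'
#' The package's central fitting function.  Runs the full calibration
#' chain in order: subpixel centerline extraction on the grid image(s),
#' the plumb-line Levenberg-Marquardt distortion fit, point+line DLT
#' homography estimation against the known grid pitch, decomposition into
#' magnification / pose / distortion-compensation offsets, deflection
#' angle estimation by stitching the X (and Y) displacement series, and
#' per-axis mechanical displacement error estimation from the four
#' directional series.  The result carries every intermediate estimate and
#' an assembled [build_compensation_model()].
#'
#' @param grid_img A grid raster (matrix), a file path, or a list of
#'   either; multiple images are fitted jointly with shared `(k, u0, v0)`.
#' @param series_x,series_y Results of [simulate_series()] (or lists with
#'   elements `frames` and `plan`) stepping along +X / +Y, used for the
#'   deflection angle; `series_x` is required.
#' @param series_x_neg,series_y_neg Optional negative-direction series;
#'   together with `series_x`/`series_y` they determine all four
#'   mechanical error directions (missing directions are recorded as zero
#'   and flagged).
#' @param grid A [grid_spec()] describing the target.
#' @param M_nominal Rated objective magnification.
#' @param pixel_pitch Physical camera pixel side (µm/pixel), assumed
#'   square.
#' @param mode Compensation mode, see [build_compensation_model()].
#' @return An object of class `stage_calib` with components `intr`,
#'   `distortion` (the `distortion_fit`), `H`, `pose`, `mag`, `delta`,
#'   `deflection` (per-pair table and average), `axis`
#'   ([axis_errors()]), `model` ([build_compensation_model()]) and
#'   `incomplete` (character vector of directions lacking a series).
#' @seealso [predict.stage_calib()], [coef.stage_calib()]
#' @export
calibrate_stage <- function(grid_img, series_x, series_y = NULL,
                            series_x_neg = NULL, series_y_neg = NULL,
                            grid = grid_spec(), M_nominal = 20,
                            pixel_pitch = 20,
                            mode = c("coherent", "paper_literal")) {
  mode <- match.arg(mode)
  imgs <- if (is.list(grid_img) && !is.matrix(grid_img)) grid_img
          else list(grid_img)
  imgs <- lapply(imgs, function(g) if (is.character(g)) read_raster(g) else g)
  s_nom <- M_nominal / pixel_pitch

  # 1-2. centerlines and plumb-line distortion fit (joint over images)
  linesets <- lapply(imgs, extract_center_lines)
  fit <- fit_distortion_joint(linesets)

  # 3-5. homography from the first (reference) image and decomposition
  corr <- grid_correspondences(fit$fits[[1]], grid,
                               px_per_um_nominal = s_nom)
  H <- estimate_homography(corr)
  ff <- focal_from_homography(H, fit$intr$u0, fit$intr$v0)
  intr <- intrinsic_params(fx = ff[["fx"]], fy = ff[["fy"]],
                           u0 = fit$intr$u0, v0 = fit$intr$v0,
                           k = fit$intr$k)
  dec <- decompose_imaging(H, intr, Lu = pixel_pitch, Lv = pixel_pitch,
                           M_nominal = M_nominal)

  # 6. deflection angle from stitched series (corner sets shared with the
  # mechanical stage below)
  dirs <- list(dxp = series_x, dxm = series_x_neg,
               dyp = series_y, dym = series_y_neg)
  corners <- lapply(dirs, function(ser) {
    if (is.null(ser)) return(NULL)
    lapply(ser$frames, function(f)
      tryCatch(.grid_corners(f, intr), error = function(e) NULL))
  })
  defl_tabs <- list()
  th <- c()
  for (nm in c("dxp", "dyp")) {
    ser <- dirs[[nm]]
    if (is.null(ser)) next
    d <- deflection_from_series(ser$frames, ser$plan,
                                px_per_um_nominal = s_nom, intr = intr,
                                corners = corners[[nm]])
    defl_tabs[[length(defl_tabs) + 1L]] <- d$pairs
    th <- c(th, d$pairs$theta_deg)
  }
  theta_deg <- mean(th)

  # 7. per-axis mechanical errors (deflection-compensated)
  s_est <- dec$mag$M / pixel_pitch
  delta_rel <- c(dxp = 0, dxm = 0, dyp = 0, dym = 0)
  raw_px <- c(dxp = NA_real_, dxm = NA_real_, dyp = NA_real_, dym = NA_real_)
  incomplete <- character(0)
  step_um <- NA_real_
  for (nm in names(dirs)) {
    ser <- dirs[[nm]]
    if (is.null(ser)) { incomplete <- c(incomplete, nm); next }
    ae <- axis_error_from_series(ser$frames, ser$plan, px_per_um = s_est,
                                 theta_deg = theta_deg, intr = intr,
                                 corners = corners[[nm]])
    delta_rel[nm] <- ae$delta_rel
    raw_px[nm] <- ae$raw_px
    step_um <- ae$step_um
  }
  axis <- axis_errors(delta_rel[["dxp"]], delta_rel[["dxm"]],
                      delta_rel[["dyp"]], delta_rel[["dym"]],
                      raw_px = as.list(raw_px), step_um = step_um,
                      px_per_um = s_est)

  model <- build_compensation_model(
    calib = list(M_prime = dec$mag$M_prime,
                 delta_x = unname(dec$delta[1]),
                 delta_y = unname(dec$delta[2])),
    theta_deg = theta_deg, axis = axis, mode = mode,
    intr = intr, pose = dec$pose)

  structure(list(intr = intr, distortion = fit$fits[[1]],
                 distortion_joint = fit, H = H, pose = dec$pose,
                 mag = dec$mag, delta = dec$delta,
                 deflection = list(pairs = do.call(rbind, defl_tabs),
                                   theta_deg = theta_deg),
                 axis = axis, model = model,
                 grid = grid, M_nominal = M_nominal,
                 pixel_pitch = pixel_pitch,
                 incomplete = incomplete),
            class = "stage_calib")
}

#' Joint plumb-line fit over several grid images
#'
#' Shares `(k, u0, v0)` across images while each image keeps its own line
#' parameters.  With a single image this is [fit_distortion()].
#'
#' @param linesets List of `center_line_set` objects.
#' @param ... Passed to [fit_distortion()].
#' @return List with `intr` (shared distortion parameters) and `fits`
#'   (per-image `distortion_fit` objects refitted at the shared
#'   parameters).
#' @export
fit_distortion_joint <- function(linesets, ...) {
  fits <- lapply(linesets, fit_distortion, ...)
  if (length(fits) == 1L)
    return(list(intr = fits[[1]]$intr, fits = fits))
  # shared parameters: refit each image with (k, u0, v0) seeded by the
  # objective-weighted mean, then one more pass holding the best common
  # value (simple two-stage scheme; images of the same camera agree)
  ks <- vapply(fits, function(f) f$intr$k, 0)
  u0s <- vapply(fits, function(f) f$intr$u0, 0)
  v0s <- vapply(fits, function(f) f$intr$v0, 0)
  init <- list(k = mean(ks), u0 = mean(u0s), v0 = mean(v0s))
  fits <- lapply(linesets, fit_distortion, init = init, ...)
  kbar <- mean(vapply(fits, function(f) f$intr$k, 0))
  u0bar <- mean(vapply(fits, function(f) f$intr$u0, 0))
  v0bar <- mean(vapply(fits, function(f) f$intr$v0, 0))
  list(intr = intrinsic_params(1, 1, u0bar, v0bar, kbar), fits = fits)
}

#' @export
print.stage_calib <- function(x, ...) {
  cat("Stage calibration\n")
  cat(sprintf("  k = %.4g px^-2, (u0, v0) = (%.2f, %.2f) px\n",
              x$intr$k, x$intr$u0, x$intr$v0))
  cat(sprintf("  M = %.4f (nominal %g), M' = %.5f\n",
              x$mag$M, x$M_nominal, x$mag$M_prime))
  cat(sprintf("  theta = %.4f deg over %d stitched pairs\n",
              x$deflection$theta_deg, nrow(x$deflection$pairs)))
  cat(sprintf("  Delta = %+.5f / %+.5f / %+.5f / %+.5f (+X/-X/+Y/-Y)\n",
              x$axis$dxp, x$axis$dxm, x$axis$dyp, x$axis$dym))
  if (length(x$incomplete))
    cat("  INCOMPLETE: no series for", paste(x$incomplete, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.stage_calib <- function(object, ...) {
  structure(list(calib = object), class = "summary.stage_calib")
}

#' @export
print.summary.stage_calib <- function(x, ...) {
  ob <- x$calib
  cat("== Image distortion compensation ==\n")
  co <- data.frame(
    parameter = c("fx (px/um)", "fy (px/um)", "u0 (px)", "v0 (px)",
                  "k (px^-2)", "M", "M'", "delta_x (um)", "delta_y (um)"),
    value = c(ob$intr$fx, ob$intr$fy, ob$intr$u0, ob$intr$v0, ob$intr$k,
              ob$mag$M, ob$mag$M_prime, ob$delta[1], ob$delta[2]))
  print(co, row.names = FALSE, digits = 6)
  cat("\n== Deflection angle (per stitched pair) ==\n")
  print(ob$deflection$pairs, row.names = FALSE, digits = 4)
  cat(sprintf("average theta: %.3f deg\n", ob$deflection$theta_deg))
  cat("\n== Mechanical displacement errors ==\n")
  print(ob$axis)
  invisible(x)
}

#' Calibrated coefficients of a stage calibration
#'
#' @param object A `stage_calib`.
#' @param ... Unused.
#' @return Named numeric vector with the five compensation coefficient
#'   groups plus the distortion parameters.
#' @export
coef.stage_calib <- function(object, ...) {
  c(M_prime = object$mag$M_prime,
    delta_x = unname(object$delta[1]), delta_y = unname(object$delta[2]),
    theta_deg = object$deflection$theta_deg,
    dxp = object$axis$dxp, dxm = object$axis$dxm,
    dyp = object$axis$dyp, dym = object$axis$dym,
    k = object$intr$k, u0 = object$intr$u0, v0 = object$intr$v0,
    fx = object$intr$fx, fy = object$intr$fy)
}

#' Compensated stage commands for desired displacements
#'
#' @param object A `stage_calib`.
#' @param newdata Two-column matrix or data.frame of desired displacements
#'   (µm).
#' @param ... Unused.
#' @return Matrix with columns `cmd_x`, `cmd_y` (µm).
#' @export
predict.stage_calib <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  stopifnot(ncol(nd) == 2)
  out <- t(apply(nd, 1, function(d)
    compensate_move(object$model, d)$command))
  colnames(out) <- c("cmd_x", "cmd_y")
  out
}

#' Diagnostic plot of a stage calibration
#'
#' Left: radial distortion correction magnitude against radius about the
#' principal point.  Right: per-pair deflection angles with their mean.
#'
#' @param x A `stage_calib`.
#' @param ... Unused.
#' @export
plot.stage_calib <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  r <- seq(0, 700, length.out = 200)
  graphics::plot(r, abs(x$intr$k) * r^3, type = "l",
                 xlab = "radius about principal point (px)",
                 ylab = "radial correction (px)",
                 main = "Distortion correction")
  tab <- x$deflection$pairs
  graphics::plot(tab$group, tab$theta_deg, pch = 19,
                 xlab = "stitched pair", ylab = "theta (deg)",
                 main = "Deflection angle")
  graphics::abline(h = x$deflection$theta_deg, lty = 2)
  invisible(x)
}
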
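# Assembly and application of the full compensation model: magnification
# ratio, distortion compensation, mounting deflection and per-axis
# mechanical errors combined into a corrected stage command.

#' Build the compensation model from calibrated coefficients
#'
#' Gathers the five compensation coefficient groups — magnification ratio
#' `M'`, distortion compensation offsets `(delta_x, delta_y)`, deflection
#' angle `theta`, and the per-axis mechanical errors behind the quadrant
#' coefficient — into a single model object, and exposes the assembled
#' error transform via [compose_error_transform()].
#'
#' Two evaluation modes exist (see [compensate_move()]):
#' `"coherent"` (default) treats `theta` strictly as the frame rotation
#' between image and stage axes and applies the per-axis gains
#' multiplicatively, which is invertible and yields zero residual under a
#' perfect model; `"paper_literal"` evaluates the printed
#' single-coefficient formula verbatim for auditability.
#'
#' @param calib Named list with the distortion-calibration block; required
#'   fields `M_prime`, `delta_x`, `delta_y` (and `k`, `u0`, `v0`, `fx`,
#'   `fy` when `intr` is not given separately).
#' @param theta_deg Deflection angle (degrees).
#' @param axis An [axis_errors()] object.
#' @param mode `"coherent"` or `"paper_literal"`.
#' @param intr Optional [intrinsic_params()] for coherent-mode local
#'   undistortion; assembled from `calib` when absent.
#' @param pose Optional [extrinsic_pose()] stored for the error transform.
#' @return An object of class `compensation_model`.
#' @export
build_compensation_model <- function(calib, theta_deg, axis,
                                     mode = c("coherent", "paper_literal"),
                                     intr = NULL, pose = extrinsic_pose()) {
  mode <- match.arg(mode)
  need <- c("M_prime", "delta_x", "delta_y")
  if (is.null(intr)) need <- c(need, "k", "u0", "v0", "fx", "fy")
  for (f in need) {
    if (is.null(calib[[f]]) || !is.finite(calib[[f]]))
      stop("calibration field missing or non-finite: ", f)
  }
  stopifnot(is.finite(theta_deg), inherits(axis, "axis_errors"))
  if (is.null(intr))
    intr <- intrinsic_params(fx = calib$fx, fy = calib$fy,
                             u0 = calib$u0, v0 = calib$v0, k = calib$k)
  structure(list(M_prime = calib$M_prime,
                 delta = c(delta_x = calib$delta_x, delta_y = calib$delta_y),
                 theta_deg = theta_deg, axis = axis, mode = mode,
                 intr = intr, pose = pose),
            class = "compensation_model")
}

#' @export
print.compensation_model <- function(x, ...) {
  cat("Stage compensation model (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  M'     = %.5f\n", x$M_prime))
  cat(sprintf("  delta  = (%.4f, %.4f) um\n", x$delta[1], x$delta[2]))
  cat(sprintf("  theta  = %.4f deg\n", x$theta_deg))
  cat(sprintf("  Delta  = %+.5f / %+.5f / %+.5f / %+.5f (+X/-X/+Y/-Y)\n",
              x$axis$dxp, x$axis$dxm, x$axis$dyp, x$axis$dym))
  invisible(x)
}

#' The assembled error transform of a compensation model
#' @param model A `compensation_model`.
#' @return 3x3 `error_transform` matrix.
#' @export
error_transform <- function(model) {
  compose_error_transform(M_prime = model$M_prime,
                          deflection = deflection_params(model$theta_deg),
                          axis = model$axis, pose = model$pose)
}

#' Convert a desired displacement into a compensated stage command
#'
#' Coherent mode inverts the calibrated error chain: the desired
#' displacement (µm, expressed in image axes under the nominal pixel
#' scale) is rotated by `-theta` into stage axes, divided per-axis by the
#' direction-selected gains `1 + delta` (quadrant chosen after the
#' rotation), and divided by `M'`.  Paper-literal mode evaluates the
#' printed compensation formula with the scalar quadrant coefficient:
#' `command = M' * delta * mu * s * (cos(theta), sin(theta))` — kept for
#' auditability of the printed arithmetic.
#'
#' @param model A `compensation_model`.
#' @param desired Desired displacement `c(dX, dY)` in µm (nonzero).
#' @return List with `command` (µm) and `predicted` (the displacement the
#'   model predicts the stage will achieve, µm).
#' @export
compensate_move <- function(model, desired) {
  stopifnot(inherits(model, "compensation_model"),
            length(desired) == 2, all(is.finite(desired)))
  if (model$mode == "paper_literal") {
    s <- sqrt(sum(desired^2))
    if (s == 0) stop("desired displacement must be nonzero")
    beta <- (atan2(desired[2], desired[1]) * 180 / pi) %% 360
    m <- mu(beta, model$axis, mode = "scalar")
    th <- model$theta_deg * pi / 180
    cmd <- unname(c(model$M_prime * model$delta[1] * m * s * cos(th),
                    model$M_prime * model$delta[2] * m * s * sin(th)))
    return(list(command = cmd, predicted = cmd))
  }
  a <- -model$theta_deg * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  v <- as.numeric(rot %*% desired)
  beta <- (atan2(v[2], v[1]) * 180 / pi) %% 360
  g <- mu(beta, model$axis, mode = "per_axis")
  if (any(abs(g) < 0.5))
    stop("implausible calibration: |1 + delta| < 0.5")
  cmd <- v / g / model$M_prime
  ach <- g * cmd * model$M_prime
  roti <- matrix(c(cos(-a), sin(-a), -sin(-a), cos(-a)), 2, 2)
  list(command = as.numeric(cmd),
       predicted = as.numeric(roti %*% ach))
}

#' The identity (no-op) compensation model
#'
#' Baseline model that forwards every desired displacement unchanged;
#' used as the uncompensated arm of paired trials.
#' @param intr Optional intrinsics (defaults to a distortion-free camera).
#' @return A `compensation_model`.
#' @export
identity_model <- function(intr = intrinsic_params()) {
  build_compensation_model(
    calib = list(M_prime = 1, delta_x = 0, delta_y = 0),
    theta_deg = 0, axis = axis_errors(), intr = intr)
}

.trial_report <- function(residual, compensated, meta) {
  structure(list(residual_x = residual[1], residual_y = residual[2],
                 residual_norm = sqrt(sum(residual^2)),
                 compensated = compensated, meta = meta),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("Trial residual: (%.4g, %.4g) um, norm %.4g um (%s)\n",
              x$residual_x, x$residual_y, x$residual_norm,
              if (x$compensated) "compensated" else "uncompensated"))
  invisible(x)
}

#' Single-shot positioning trial against a synthetic ground truth
#'
#' Emulates the click-to-centre test: a point of interest at `target_px`
#' should be brought to the image origin.  The pixel offset is converted
#' to a desired physical displacement through the model's local
#' undistortion and the nominal pixel scale, compensated into a stage
#' command, pushed through the true stage model, and the remaining offset
#' from the origin is reported in micrometres.
#'
#' @param model A `compensation_model` (use [identity_model()] for the
#'   uncompensated arm).
#' @param truth A [ground_truth()] object.
#' @param target_px Target image point `c(u, v)` (px); drawn uniformly
#'   from the central region under `seed` when `NULL`.
#' @param origin_px Image origin (px); defaults to the truth's principal
#'   point.
#' @param seed Seed for target drawing.
#' @return A `trial_report` with residuals in µm.
#' @export
single_shot_trial <- function(model, truth, target_px = NULL,
                              origin_px = NULL, seed = NULL) {
  stopifnot(inherits(model, "compensation_model"),
            inherits(truth, "ground_truth"))
  if (is.null(origin_px)) origin_px <- c(truth$intr$u0, truth$intr$v0)
  if (is.null(target_px)) {
    if (is.null(seed)) stop("either target_px or seed must be given")
    target_px <- .with_seed(seed, function()
      origin_px + c(stats::runif(1, -450, 450), stats::runif(1, -300, 300)))
  }
  s_true <- px_per_um(truth)
  s_nom <- truth$M_nominal / truth$pixel_pitch
  # model's view: theoretical offset needed, in image axes, nominal scale
  t_theo <- undistort_point(target_px, model$intr)
  o_theo <- undistort_point(origin_px, model$intr)
  desired <- (o_theo - t_theo) / s_nom
  cmd <- compensate_move(model, desired)$command
  actual <- forward_stage_model(truth, cmd)
  # true image displacement of the scene (theoretical coordinates)
  th <- truth$theta_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift_px <- s_true * as.numeric(rot %*% actual)
  t_true <- undistort_point(target_px, truth$intr)
  o_true <- undistort_point(origin_px, truth$intr)
  residual_px <- (t_true + shift_px) - o_true
  .trial_report(residual_px / s_true,
                compensated = !identical(model$mode, "identity") &&
                  !(model$M_prime == 1 && model$theta_deg == 0 &&
                      all(c(model$axis$dxp, model$axis$dxm,
                            model$axis$dyp, model$axis$dym) == 0) &&
                      model$intr$k == 0),
                meta = list(target_px = target_px, seed = seed))
}

#' Cumulative-error trial over a closed stepping path
#'
#' Drives the stage around a closed rectangular path (`n` steps of 600 µm
#' along +X, then +Y, then back along -X and -Y, `4n + 1` frames for path
#' class `n`), rendering only the first and last frames, and measures
#' their stitching mismatch — zero for an error-free stage — before or
#' after compensation.
#'
#' @param model A `compensation_model`.
#' @param truth A [ground_truth()] object.
#' @param plan_class Path class 1..5 (class `n` takes `n` steps per
#'   direction; total images `4n + 1`).
#' @param spec [grid_spec()] used for rendering; defaults to the periodic
#'   ruling so long paths stay on-target.
#' @param compensated Apply the model (`TRUE`) or command the nominal
#'   steps directly (`FALSE`).
#' @param step_um Nominal step (µm).
#' @param seed Optional seed overriding the truth's (per-replicate noise).
#' @param crop Central crop side (px) used for the first/last stitching.
#' @return A `trial_report` with the mismatch in µm.
#' @export
cumulative_trial <- function(model, truth, plan_class,
                             spec = grid_spec(n_squares = Inf),
                             compensated = TRUE, step_um = 600,
                             seed = NULL, crop = 384L) {
  stopifnot(plan_class %in% 1:5)
  if (!is.null(seed)) truth$seed <- as.integer(seed)
  n <- as.integer(plan_class)
  steps <- rbind(
    matrix(rep(c(step_um, 0), n), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, step_um), n), ncol = 2, byrow = TRUE),
    matrix(rep(c(-step_um, 0), n), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, -step_um), n), ncol = 2, byrow = TRUE))
  pos <- c(0, 0)
  for (i in seq_len(nrow(steps))) {
    cmd <- if (compensated) compensate_move(model, steps[i, ])$command
           else steps[i, ]
    pos <- pos + forward_stage_model(truth, cmd)
  }
  first <- render_grid_image(truth, spec, c(0, 0), frame = 0L)
  last <- render_grid_image(truth, spec, pos, frame = nrow(steps))
  ctr_r <- floor(nrow(first) / 2); ctr_c <- floor(ncol(first) / 2)
  half <- crop %/% 2L
  rows <- (ctr_r - half):(ctr_r + half - 1L)
  cols <- (ctr_c - half):(ctr_c + half - 1L)
  s_true <- px_per_um(truth)
  search <- max(4, 0.45 * spec$pitch_um * s_true)
  o <- estimate_offset(first[rows, cols], last[rows, cols],
                       method = "xcorr", init = c(0, 0), search = search)
  .trial_report(c(o$dx, o$dy) / s_true, compensated = compensated,
                meta = list(plan_class = plan_class, n_images = 4L * n + 1L,
                            path_um = 4L * n * step_um, seed = seed))
}

#' Serialize / restore a compensation model
#'
#' Versioned JSON round-trip of all model coefficients.
#' @param model A `compensation_model`.
#' @param path Output (input) file path.
#' @return `read_compensation_model` returns the restored model;
#'   `write_compensation_model` returns `path` invisibly.
#' @export
write_compensation_model <- function(model, path) {
  obj <- list(schema_version = "stagecal-model-1",
              M_prime = model$M_prime,
              delta_x = unname(model$delta[1]),
              delta_y = unname(model$delta[2]),
              theta_deg = model$theta_deg,
              axis = model$axis[c("dxp", "dxm", "dyp", "dym")],
              mode = model$mode,
              intr = unclass(model$intr)[c("fx", "fy", "u0", "v0", "k")],
              R = model$pose$R, t = model$pose$t, t_hat = model$pose$t_hat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_compensation_model
#' @export
read_compensation_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, "stagecal-model-1"))
    stop("unknown model schema version: ", obj$schema_version)
  build_compensation_model(
    calib = list(M_prime = obj$M_prime, delta_x = obj$delta_x,
                 delta_y = obj$delta_y),
    theta_deg = obj$theta_deg,
    axis = axis_errors(obj$axis$dxp, obj$axis$dxm, obj$axis$dyp, obj$axis$dym),
    mode = obj$mode,
    intr = intrinsic_params(obj$intr$fx, obj$intr$fy, obj$intr$u0,
                            obj$intr$v0, obj$intr$k),
    pose = extrinsic_pose(R = matrix(unlist(obj$R), 3, 3),
                          t = obj$t, t_hat = obj$t_hat))
}
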
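#' Specification of the calibration grid target
#'
#' Geometry of the square calibration grid on the scale plate and the raster
#' it is imaged onto.  The default mirrors a high-precision scale whose
#' centre carries 20 x 20 squares of 50 µm side length, imaged at
#' 1200 x 900 px.  `n_squares = Inf` renders an unbounded periodic ruling
#' (the extended graduation of a long scale), which displacement series
#' need when the stage travels beyond the central grid.
#'
#' @param n_squares Squares per side (>= 2), or `Inf` for a periodic ruling.
#' @param pitch_um Square side length (µm).
#' @param image_w,image_h Raster size (pixel).
#' @param line_width_px Rendered line thickness (pixel).
#' @param major_every Every `major_every`-th line (counted from the grid
#'   centre) is a major graduation drawn `major_factor` times thicker, as
#'   on a real scale plate; this super-period is what makes stitching
#'   offsets larger than half a pitch unambiguous.  `0` disables majors.
#' @param major_factor Width multiplier of major graduations.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_squares = 20, pitch_um = 50,
                      image_w = 1200, image_h = 900,
                      line_width_px = 3, major_every = 5L,
                      major_factor = 2) {
  stopifnot(n_squares >= 2, pitch_um > 0, image_w > 0, image_h > 0,
            line_width_px > 0, major_every >= 0, major_factor >= 1)
  structure(list(n_squares = n_squares, pitch_um = pitch_um,
                 image_w = as.integer(image_w), image_h = as.integer(image_h),
                 line_width_px = line_width_px,
                 major_every = as.integer(major_every),
                 major_factor = major_factor),
            class = "grid_spec")
}

#' Ground truth for the synthetic stage/camera system
#'
#' All generative parameters of the simulator: camera intrinsics (including
#' the radial distortion factor), the true mounting deflection angle, true
#' and nominal magnification, the physical camera pixel pitch, the per-axis
#' mechanical displacement errors, the additive intensity noise level, and
#' the seed that makes every raster reproducible byte for byte.
#'
#' The pixel scale on the stage plane is `M_true / pixel_pitch` px/µm
#' (1 px/µm at the defaults: 20x magnification onto 20 µm sensor pixels,
#' so a 600 µm step shifts the image by half of a 1200 px frame).
#'
#' @param intr [intrinsic_params()]; defaults place the principal point at
#'   the centre of the default raster with `k = 5e-8` px^-2.
#' @param theta_deg True deflection angle between image and stage axes
#'   (degrees).
#' @param M_true,M_nominal Actual and rated objective magnification.
#' @param pixel_pitch Physical sensor pixel side (µm/pixel).
#' @param axis [axis_errors()] with the true relative displacement errors.
#' @param noise_sigma Additive Gaussian intensity noise (8-bit units).
#' @param seed Integer seed driving all simulator randomness.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(intr = intrinsic_params(fx = 1, fy = 1,
                                                 u0 = 599.5, v0 = 449.5,
                                                 k = 5e-8),
                         theta_deg = 0, M_true = 20, M_nominal = 20,
                         pixel_pitch = 20, axis = axis_errors(),
                         noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(intr, "intrinsic_params"), is.finite(theta_deg),
            M_true > 0, M_nominal > 0, pixel_pitch > 0,
            inherits(axis, "axis_errors"), noise_sigma >= 0)
  structure(list(intr = intr, theta_deg = theta_deg, M_true = M_true,
                 M_nominal = M_nominal, pixel_pitch = pixel_pitch,
                 axis = axis, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Pixel scale of a ground truth (pixel per micrometre)
#' @param truth A [ground_truth()] object.
#' @export
px_per_um <- function(truth) truth$M_true / truth$pixel_pitch

#' Plan for a stepped displacement series
#'
#' @param axis `"x"` or `"y"`.
#' @param direction `+1` or `-1`.
#' @param n_steps Number of steps (frames = `n_steps + 1`).
#' @param step_um Nominal step length (µm); the default of 600 µm gives
#'   consecutive frames a half-frame overlap at the default pixel scale.
#' @return An object of class `displacement_plan`.
#' @export
displacement_plan <- function(axis = c("x", "y"), direction = 1L,
                              n_steps = 10L, step_um = 600) {
  axis <- match.arg(axis)
  stopifnot(direction %in% c(-1L, 1L), n_steps >= 1, step_um > 0)
  structure(list(axis = axis, direction = as.integer(direction),
                 n_steps = as.integer(n_steps), step_um = step_um),
            class = "displacement_plan")
}

# run body with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, body) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  body()
}

#' Render a synthetic grid image
#'
#' Renders the calibration grid as seen by the modelled camera with the
#' stage displaced by `stage_pos`.  The render pipeline inverts the imaging
#' chain per pixel: each observed pixel is mapped to theoretical image
#' coordinates through the radial distortion model, rotated by
#' `-theta_deg` and divided by the pixel scale to reach stage-plane
#' coordinates, where grid-line coverage is evaluated with anti-aliased
#' (trapezoidal) profiles so that intensity-weighted centroids recover the
#' line centres to subpixel accuracy.  Dark lines (intensity 50) on a
#' bright background (200), clipped to \[0, 255\] after optional Gaussian
#' noise.
#'
#' Image convention: `(u, v) = (column, row)`, 0-based, origin at the
#' top-left; the stage +Y axis maps to +v at zero deflection.
#'
#' @param truth A [ground_truth()] object.
#' @param spec A [grid_spec()] object.
#' @param stage_pos Stage position `c(X, Y)` in µm.
#' @param frame Frame index mixed into the noise stream so that each frame
#'   of a series gets independent, reproducible noise.
#' @return Numeric matrix `image_h x image_w` of intensities in \[0, 255\]
#'   (row = v + 1, column = u + 1).
#' @export
render_grid_image <- function(truth, spec = grid_spec(),
                              stage_pos = c(0, 0), frame = 0L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "grid_spec"),
            length(stage_pos) == 2, all(is.finite(stage_pos)))
  s <- px_per_um(truth)
  if (is.finite(spec$n_squares)) {
    extent <- spec$n_squares * spec$pitch_um
    if (extent * s > 2 * max(spec$image_w, spec$image_h))
      stop("grid does not fit the raster at this magnification")
  }
  w <- spec$image_w; h <- spec$image_h
  u <- rep(seq_len(w) - 1, each = h)   # column-major over the h x w matrix
  v <- rep(seq_len(h) - 1, times = w)
  th <- undistort_point(cbind(u, v), truth$intr)
  # image -> stage plane: remove centre offset, rotate by -theta, scale
  cu <- (w - 1) / 2; cv <- (h - 1) / 2
  a <- truth$theta_deg * pi / 180
  du <- (th[, 1] - cu) / s
  dv <- (th[, 2] - cv) / s
  X <- cos(a) * du + sin(a) * dv - stage_pos[1]
  Y <- -sin(a) * du + cos(a) * dv - stage_pos[2]
  margin <- (spec$line_width_px * max(1, spec$major_factor) / 2 + 0.5) / s
  # per-line width: major graduations (world index divisible by
  # major_every, centre line being index 0) are drawn thicker
  half_w <- function(j) {
    hw <- rep(spec$line_width_px / 2, length(j))
    if (spec$major_every > 0)
      hw[j %% spec$major_every == 0] <- hw[j %% spec$major_every == 0] *
        spec$major_factor
    hw
  }
  if (is.finite(spec$n_squares)) {
    halfext <- spec$n_squares * spec$pitch_um / 2
    jx <- pmin(pmax(round((X + halfext) / spec$pitch_um), 0), spec$n_squares)
    jy <- pmin(pmax(round((Y + halfext) / spec$pitch_um), 0), spec$n_squares)
    d_vline <- abs(X + halfext - jx * spec$pitch_um) * s   # px distance
    d_hline <- abs(Y + halfext - jy * spec$pitch_um) * s
    jx <- jx - spec$n_squares %/% 2L
    jy <- jy - spec$n_squares %/% 2L
    in_y <- Y >= -halfext - margin & Y <= halfext + margin
    in_x <- X >= -halfext - margin & X <= halfext + margin
  } else {
    jx <- round(X / spec$pitch_um)
    jy <- round(Y / spec$pitch_um)
    d_vline <- abs(X - jx * spec$pitch_um) * s
    d_hline <- abs(Y - jy * spec$pitch_um) * s
    in_y <- TRUE; in_x <- TRUE
  }
  cov_v <- pmin(pmax(half_w(jx) + 0.5 - d_vline, 0), 1) * in_y
  cov_h <- pmin(pmax(half_w(jy) + 0.5 - d_hline, 0), 1) * in_x
  coverage <- pmax(cov_v, cov_h)
  img <- 200 + (50 - 200) * coverage
  if (truth$noise_sigma > 0) {
    noise <- .with_seed(
      (truth$seed %% 1000003L) * 2048L + (as.integer(frame) %% 2048L),
      function() stats::rnorm(length(img), 0, truth$noise_sigma))
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), 255)
  matrix(img, nrow = h, ncol = w)
}

#' True achieved displacement for a commanded stage move
#'
#' Applies the stage's per-axis relative displacement errors: each command
#' component is scaled by `(1 + delta)` with `delta` chosen by the
#' component's sign (+X/-X, +Y/-Y).  The deflection angle does not enter
#' here: it acts between stage and image coordinates, not on the stage
#' mechanics.
#'
#' @param truth A [ground_truth()] object.
#' @param command Commanded displacement `c(dX, dY)` in µm.
#' @return Actual displacement `c(dX, dY)` in µm.
#' @export
forward_stage_model <- function(truth, command) {
  stopifnot(length(command) == 2, all(is.finite(command)))
  ax <- truth$axis
  dx <- if (command[1] >= 0) ax$dxp else ax$dxm
  dy <- if (command[2] >= 0) ax$dyp else ax$dym
  c(command[1] * (1 + dx), command[2] * (1 + dy))
}

#' Simulate a stepped displacement image series
#'
#' Renders `n_steps + 1` frames.  Frame i is taken after i nominal steps;
#' the actual position accumulates each step through
#' [forward_stage_model()], so a relative error of -0.01 leaves every
#' 600 µm step 6 µm short.
#'
#' @param truth A [ground_truth()] object.
#' @param spec A [grid_spec()] object (use `n_squares = Inf` for series
#'   that travel beyond the central grid).
#' @param plan A [displacement_plan()] object.
#' @return A list with `frames` (list of rasters), `commanded` (matrix of
#'   commanded positions, µm), `actual` (matrix of true positions, µm) and
#'   the `plan`.
#' @export
simulate_series <- function(truth, spec = grid_spec(n_squares = Inf),
                            plan = displacement_plan()) {
  stopifnot(inherits(plan, "displacement_plan"))
  step <- c(0, 0)
  if (plan$axis == "x") step[1] <- plan$direction * plan$step_um
  else step[2] <- plan$direction * plan$step_um
  n <- plan$n_steps + 1L
  commanded <- matrix(0, n, 2)
  actual <- matrix(0, n, 2)
  frames <- vector("list", n)
  pos <- c(0, 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      commanded[i, ] <- commanded[i - 1, ] + step
      pos <- pos + forward_stage_model(truth, step)
      actual[i, ] <- pos
    }
    frames[[i]] <- render_grid_image(truth, spec, actual[i, ], frame = i - 1L)
  }
  list(frames = frames, commanded = commanded, actual = actual, plan = plan)
}

#' Write a simulated series to disk with a ground-truth sidecar
#'
#' Saves each frame as PNG (or TIFF) plus a `truth.json` sidecar holding
#' every generative parameter, for use by external harnesses.
#'
#' @param series Result of [simulate_series()].
#' @param truth The [ground_truth()] used.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the vector of written frame paths.
#' @export
write_series <- function(series, truth, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(series$frames))
  for (i in seq_along(series$frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%03d.%s", i - 1,
                                       if (format == "png") "png" else "tif"))
    write_raster(series$frames[[i]], paths[i])
  }
  sidecar <- list(
    intr = unclass(truth$intr), theta_deg = truth$theta_deg,
    M_true = truth$M_true, M_nominal = truth$M_nominal,
    pixel_pitch = truth$pixel_pitch,
    axis = truth$axis[c("dxp", "dxm", "dyp", "dym")],
    noise_sigma = truth$noise_sigma, seed = truth$seed,
    commanded = series$commanded, actual = series$actual)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
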
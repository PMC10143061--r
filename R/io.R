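# Raster and calibration-file I/O.  Rasters are matrices (rows = v), read
# into [0, 1]; calibration artifacts are versioned JSON so results can be
# diffed.  Angles are stored in degrees in files, radians only internally.

#' Read a grayscale raster
#'
#' Reads TIFF or PNG into a 2-D intensity matrix in \[0, 1\] (full scale of
#' the stored bit depth maps to 1).  RGB inputs are converted by the Rec.
#' 601 luminance weights.
#'
#' @param path File path (.png, .tif, .tiff).
#' @return Numeric matrix (rows = v, columns = u).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' for ", path))
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  img
}

#' Write a grayscale raster
#'
#' Intensities above 1.5 are assumed 8-bit scale and divided by 255; TIFF
#' output uses 32-bit float samples (lossless for simulator output), PNG
#' is 8-bit.
#'
#' @param img Numeric matrix.
#' @param path Output path (.png, .tif, .tiff).
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  img <- .norm_img(img)
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L),
    stop("unsupported raster format '", ext, "' for ", path))
  invisible(path)
}

#' Write / read the calibration file
#'
#' Versioned JSON holding every section of a [calibrate_stage()] result:
#' intrinsics, magnification, deflection (per-pair table and average, in
#' degrees), mechanical axis errors, and provenance.
#'
#' @param calib A `stage_calib`.
#' @param path File path.
#' @param provenance Optional named list (input paths, seeds) stored
#'   verbatim.
#' @return `read_calibration` returns a named list mirroring the file;
#'   `write_calibration` returns `path` invisibly.
#' @export
write_calibration <- function(calib, path, provenance = list()) {
  stopifnot(inherits(calib, "stage_calib"))
  obj <- list(
    schema_version = "stagecal-calib-1",
    intrinsics = unclass(calib$intr)[c("fx", "fy", "u0", "v0", "k")],
    magnification = calib$mag,
    delta = as.list(calib$delta),
    deflection = list(pairs = calib$deflection$pairs,
                      theta_deg = calib$deflection$theta_deg),
    axis_errors = c(calib$axis[c("dxp", "dxm", "dyp", "dym")],
                    list(raw_px = calib$axis$raw_px,
                         step_um = calib$axis$step_um,
                         px_per_um = calib$axis$px_per_um)),
    pose = list(R = calib$pose$R, t = calib$pose$t, t_hat = calib$pose$t_hat),
    distortion_fit = list(objective = calib$distortion$objective_value,
                          converged = calib$distortion$converged,
                          n_iterations = calib$distortion$n_iterations),
    incomplete = calib$incomplete,
    provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, "stagecal-calib-1"))
    stop("unknown calibration schema version: ", obj$schema_version)
  num_leaves <- unlist(obj[c("intrinsics", "magnification", "delta",
                             "axis_errors")])
  num_leaves <- suppressWarnings(as.numeric(num_leaves))
  if (anyNA(num_leaves))
    stop("calibration file contains non-finite numeric fields")
  obj
}

#' Run the full calibration pipeline from a configuration
#'
#' Stage order: centerline extraction, distortion fit, homography,
#' decomposition, deflection stitching, mechanical errors, model assembly.
#' Each stage is logged with a stage tag; any failure aborts with the
#' stage name.  A configuration missing the Y series still calibrates but
#' marks the mechanical section incomplete and (by default) raises an
#' error at the end.
#'
#' @param config Named list: `grid_images` (paths or matrices), `series`
#'   (named list `x`, `x_neg`, `y`, `y_neg`, each a list with `frames` —
#'   rasters or paths — and `plan` fields `axis`, `direction`, `step_um`),
#'   `M_nominal`, `pixel_pitch`, optional `grid` fields, optional `seed`.
#' @param out Optional path for the calibration JSON.
#' @param allow_incomplete Keep going when directional series are missing.
#' @param quiet Suppress stage logging.
#' @return The `stage_calib` object (with the calibration file written
#'   when `out` is given).
#' @export
run_pipeline <- function(config, out = NULL, allow_incomplete = FALSE,
                         quiet = FALSE) {
  log_stage <- function(tag, msg)
    if (!quiet) message(sprintf("[%s] %s", tag, msg))
  get_series <- function(nm) {
    s <- config$series[[nm]]
    if (is.null(s)) return(NULL)
    frames <- lapply(s$frames, function(f)
      if (is.character(f)) read_raster(f) else f)
    plan <- displacement_plan(axis = s$plan$axis,
                              direction = s$plan$direction,
                              n_steps = length(frames) - 1L,
                              step_um = s$plan$step_um)
    list(frames = frames, plan = plan)
  }
  grid <- do.call(grid_spec, config$grid %||% list())
  log_stage("lines", "extracting centerlines and fitting distortion")
  calib <- calibrate_stage(
    grid_img = config$grid_images,
    series_x = get_series("x"), series_y = get_series("y"),
    series_x_neg = get_series("x_neg"), series_y_neg = get_series("y_neg"),
    grid = grid,
    M_nominal = config$M_nominal %||% 20,
    pixel_pitch = config$pixel_pitch %||% 20)
  log_stage("distortion", sprintf("k = %.4g px^-2", calib$intr$k))
  log_stage("homography", sprintf("M' = %.5f", calib$mag$M_prime))
  log_stage("deflection", sprintf("theta = %.4f deg", calib$deflection$theta_deg))
  log_stage("mechanical", sprintf("Delta = %+.5f/%+.5f/%+.5f/%+.5f",
                                  calib$axis$dxp, calib$axis$dxm,
                                  calib$axis$dyp, calib$axis$dym))
  log_stage("model", "compensation model assembled")
  if (length(calib$incomplete) && !allow_incomplete)
    stop("mechanical section incomplete: no series for ",
         paste(calib$incomplete, collapse = ", "))
  if (!is.null(out)) {
    write_calibration(calib, out,
                      provenance = list(seed = config$seed,
                                        timestamp = format(Sys.time())))
    log_stage("write", out)
  }
  calib
}

`%||%` <- function(a, b) if (is.null(a)) b else a
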
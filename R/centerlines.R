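# Subpixel grid centerline extraction.
#
# Strategy: scanlines perpendicular to each line family.  For the vertical
# family every image row is scanned for dark runs; each run's
# intensity-weighted centroid gives one subpixel sample of a line centre.
# Rows crossing a horizontal grid line go dark over long runs and are
# rejected by the run-width bound, so intersection regions contribute no
# samples.  Samples are grouped into lines by greedy tracking (nearest
# active track; grid pitch >> per-scanline drift).  The horizontal family
# is handled identically on the transpose.

.norm_img <- function(img) {
  img <- as.matrix(img)
  if (max(img, na.rm = TRUE) > 1.5) img <- img / 255
  img
}

# centroid samples along one scan orientation; returns matrix (along, across)
# runs touching the scan boundary are truncated line crossings and skipped
.scan_centroids <- function(img, thr, bg, max_run) {
  nr <- nrow(img)
  out <- vector("list", nr)
  for (i in seq_len(nr)) {
    row <- img[i, ]
    r <- rle(row < thr)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    sel <- which(r$values & r$lengths <= max_run &
                   starts > 1L & ends < length(row))
    if (!length(sel)) next
    cs <- numeric(length(sel))
    keep <- logical(length(sel))
    for (j in seq_along(sel)) {
      a <- max(1L, starts[sel[j]] - 1L)
      b <- min(length(row), ends[sel[j]] + 1L)
      wgt <- pmax(bg - row[a:b], 0)
      sw <- sum(wgt)
      if (sw <= 0) next
      cs[j] <- sum(wgt * (a:b)) / sw - 1  # 0-based pixel coordinate
      keep[j] <- TRUE
    }
    if (any(keep)) out[[i]] <- cbind(scan = i - 1, pos = cs[keep])
  }
  do.call(rbind, out)
}

# group (scan, pos) samples into lines by de-sloped 1-D clustering:
# estimate the family's dominant drift (px of pos per scanline) from
# nearest-neighbour matches between consecutive scanlines, remove it, and
# split the de-sloped positions at gaps wider than `gap`.  Samples whose
# residual against a per-cluster cubic (which absorbs the smooth radial
# distortion bow) is large are contaminated — typically dark runs merged
# with the slanted perpendicular family near crossings — and dropped.
.group_lines <- function(samples, min_points, gap = 10, trim = TRUE) {
  if (is.null(samples) || !nrow(samples)) return(list())
  samples <- samples[order(samples[, 1], samples[, 2]), , drop = FALSE]
  scan <- samples[, 1]; pos <- samples[, 2]
  # dominant drift from consecutive-scan nearest matches
  by_scan <- split(pos, scan)
  sc_keys <- as.numeric(names(by_scan))
  pairs <- which(diff(sc_keys) >= 1 & diff(sc_keys) <= 2)
  if (length(pairs) > 80)
    pairs <- pairs[unique(round(seq(1, length(pairs), length.out = 80)))]
  slopes <- unlist(lapply(pairs, function(i) {
    ds <- sc_keys[i + 1] - sc_keys[i]
    a <- by_scan[[i]]; b <- sort(by_scan[[i + 1]])
    j <- pmin(pmax(findInterval(a, b), 1L), length(b))
    jn <- pmin(j + 1L, length(b))
    d <- ifelse(abs(b[j] - a) <= abs(b[jn] - a), b[j] - a, b[jn] - a)
    d[abs(d) <= 3] / ds
  }))
  m <- if (length(slopes)) stats::median(slopes) else 0
  det <- pos - m * scan
  ord <- order(det)
  cl <- cumsum(c(1, diff(det[ord]) > gap))
  out <- list()
  for (id in unique(cl)) {
    sel <- ord[cl == id]
    if (length(sel) < min_points) next
    s <- scan[sel]; p <- pos[sel]
    if (trim && length(sel) >= 12) {
      fit <- stats::lm.fit(cbind(1, s, s^2, s^3), p)
      r <- fit$residuals
      tol <- max(0.35, 6 * stats::mad(r))
      keep <- abs(r) <= tol
      if (sum(keep) < min_points) next
      s <- s[keep]; p <- p[keep]
    }
    out[[length(out) + 1L]] <- cbind(scan = s, pos = p)
  }
  out
}

# total-least-squares line fit; returns list(alpha, phi, dir, centroid)
# in Hessian normal form: u cos(alpha) + v sin(alpha) + phi = 0
.tls_line <- function(pts) {
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  e <- eigen(crossprod(d) / nrow(pts), symmetric = TRUE)
  dir <- e$vectors[, 1]           # dominant direction
  nrm <- e$vectors[, 2]           # normal
  alpha <- atan2(nrm[2], nrm[1])
  if (alpha > pi / 2) { alpha <- alpha - pi; nrm <- -nrm }
  if (alpha <= -pi / 2) { alpha <- alpha + pi; nrm <- -nrm }
  phi <- -sum(nrm * ctr)
  list(alpha = alpha, phi = phi, dir = dir, centroid = ctr,
       rms = sqrt(e$values[2]))
}

.make_center_line <- function(pts, orientation) {
  fit <- .tls_line(pts)
  structure(list(points = pts, m = nrow(pts),
                 alpha = fit$alpha, phi = fit$phi,
                 orientation = orientation,
                 rms = fit$rms, centroid = fit$centroid),
            class = "center_line")
}

#' Extract subpixel grid centerlines from a raster
#'
#' Detects the dark grid lines of a calibration-grid image and returns one
#' centerline per detected line, with subpixel centres from
#' intensity-weighted centroids taken along scanlines perpendicular to the
#' line family.  Lines are grouped into the horizontal and vertical
#' families and ordered by their position at the image centre.
#'
#' @param img Raster matrix (rows = v, columns = u), intensities in
#'   \[0, 1\] or \[0, 255\].
#' @param min_points Minimum samples for a track to count as a line.
#' @param max_run Maximum dark-run width (px) accepted as a line crossing.
#' @return An object of class `center_line_set`: a list with elements
#'   `vertical` and `horizontal` (lists of `center_line` objects, each with
#'   `points` (n x 2 matrix of 0-based `(u, v)`), `m`, `alpha`, `phi`,
#'   `orientation`), plus the attribute `image_size = c(w, h)`.
#' @export
extract_center_lines <- function(img, min_points = 30L, max_run = 12L) {
  img <- .norm_img(img)
  rng <- range(img)
  if (diff(rng) < 0.15)
    stop("contrast too low: no grid lines found (intensity range ",
         sprintf("%.3f", diff(rng)), ")")
  bg <- stats::quantile(img, 0.75, names = FALSE)
  dark <- stats::quantile(img, 0.01, names = FALSE)
  thr <- (bg + dark) / 2
  # vertical lines: scan rows; samples are (v, u)
  sv <- .scan_centroids(img, thr, bg, max_run)
  # horizontal lines: scan columns; samples are (u, v)
  sh <- .scan_centroids(t(img), thr, bg, max_run)
  mk_family <- function(samples, orientation) {
    tr <- .group_lines(samples, min_points)
    lines <- lapply(tr, function(x) {
      pts <- if (orientation == "vertical")
        cbind(u = x[, 2], v = x[, 1]) else cbind(u = x[, 1], v = x[, 2])
      .make_center_line(pts[order(pts[, if (orientation == "vertical") 2 else 1]), ,
                            drop = FALSE], orientation)
    })
    # order by position at the image centre
    if (length(lines)) {
      ctr <- if (orientation == "vertical") (ncol(img) - 1) / 2 else (nrow(img) - 1) / 2
      pos <- vapply(lines, function(l) line_position(l, at = ctr), 0)
      lines <- lines[order(pos)]
    }
    lines
  }
  vert <- mk_family(sv, "vertical")
  horiz <- mk_family(sh, "horizontal")
  if (!length(vert) && !length(horiz))
    stop("no grid lines found: ", nrow(rbind(sv, sh)),
         " candidate samples formed no track of >= ", min_points, " points")
  structure(list(vertical = vert, horizontal = horiz),
            class = "center_line_set",
            image_size = c(ncol(img), nrow(img)))
}

#' Position of a centerline where it crosses the image centre
#'
#' For a vertical line, the u coordinate at `v = at`; for a horizontal
#' line, the v coordinate at `u = at`.
#' @param line A `center_line`.
#' @param at Coordinate along the line's dominant axis.
#' @export
line_position <- function(line, at) {
  ca <- cos(line$alpha); sa <- sin(line$alpha)
  if (line$orientation == "vertical") -(line$phi + at * sa) / ca
  else -(line$phi + at * ca) / sa
}

#' @export
print.center_line_set <- function(x, ...) {
  cat(sprintf("Grid centerlines: %d vertical, %d horizontal (image %d x %d)\n",
              length(x$vertical), length(x$horizontal),
              attr(x, "image_size")[1], attr(x, "image_size")[2]))
  invisible(x)
}

#' Grid rotation implied by a centerline family
#'
#' Mean rotation angle of the grid implied by the orientation of the lines
#' of one family: a vertical grid line rotated by `theta` runs along
#' `(-sin(theta), cos(theta))` in `(u, v)`, a horizontal one along
#' `(cos(theta), sin(theta))`.
#'
#' @param lines A `center_line_set`.
#' @param family `"vertical"` or `"horizontal"`.
#' @return Mean implied rotation (degrees).
#' @export
family_tilt <- function(lines, family = c("vertical", "horizontal")) {
  family <- match.arg(family)
  fam <- lines[[family]]
  if (!length(fam)) stop("no lines in the ", family, " family")
  th <- vapply(fam, function(l) {
    d <- .tls_line(l$points)$dir
    if (family == "vertical") {
      if (d[2] < 0) d <- -d
      atan2(-d[1], d[2])
    } else {
      if (d[1] < 0) d <- -d
      atan2(d[2], d[1])
    }
  }, 0)
  mean(th) * 180 / pi
}
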
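# Pairwise translation registration of overlapping frames, and the camera
# deflection angle derived from stitching offsets across stage steps.
#
# Two backends:
#  * "corner"  — grid-corner features (centerline intersections) matched by
#    a mode-of-differences consensus: the translation voted for by the most
#    corner pairs wins, refined as the mean of its inliers (1 px
#    threshold).  This is the robust-consensus role the SIFT+RANSAC
#    stitching of the hardware system plays, specialised to grid targets.
#  * "xcorr"  — zero-padded (linear) cross-correlation via FFT with
#    parabolic subpixel peak interpolation; content-agnostic fallback.
#
# Grid images are periodic, so an unconstrained estimate can lock onto the
# wrong grid cell; when the nominal offset is known it is passed as `init`
# and both backends search near it, and in "auto" mode the two backends
# are cross-checked against half a grid period.

.grid_corners <- function(img, intr = NULL, lines = NULL) {
  if (is.null(lines)) lines <- extract_center_lines(img)
  fit_fam <- function(fam) {
    lapply(fam, function(l) {
      pts <- l$points
      if (!is.null(intr)) pts <- undistort_point(pts, intr)
      .tls_line(pts)
    })
  }
  fv <- fit_fam(lines$vertical); fh <- fit_fam(lines$horizontal)
  if (!length(fv) || !length(fh))
    stop("registration error: no grid corners (need both line families)")
  out <- matrix(NA_real_, length(fv) * length(fh), 2)
  r <- 0L
  for (a in fv) for (b in fh) {
    Mm <- rbind(c(cos(a$alpha), sin(a$alpha)), c(cos(b$alpha), sin(b$alpha)))
    r <- r + 1L
    out[r, ] <- solve(Mm, -c(a$phi, b$phi))
  }
  out
}

.corner_offset <- function(cA, cB, init, search, tol = 1) {
  # all-pairs differences; candidate translations from high-count 2-px
  # bins, each refined by mean-of-inliers; the candidate keeping the most
  # 1-px inliers wins (grid periodicity makes runner-up bins aliases)
  d1 <- outer(cB[, 1], cA[, 1], "-")
  d2 <- outer(cB[, 2], cA[, 2], "-")
  keep <- abs(d1 - init[1]) <= search & abs(d2 - init[2]) <= search
  if (!any(keep)) return(NULL)
  d <- cbind(d1[keep], d2[keep])
  key <- paste(round(d[, 1] / 2), round(d[, 2] / 2))
  counts <- table(key)
  cand_keys <- names(sort(counts, decreasing = TRUE))
  cand_keys <- cand_keys[counts[cand_keys] >= max(3, 0.5 * max(counts))]
  cand_keys <- utils::head(cand_keys, 12L)
  cands <- list()
  for (kk in cand_keys) {
    ctr <- colMeans(d[key == kk, , drop = FALSE])
    inl <- FALSE
    for (it in 1:3) {
      inl <- abs(d[, 1] - ctr[1]) <= tol & abs(d[, 2] - ctr[2]) <= tol
      if (!any(inl)) break
      ctr <- colMeans(d[inl, , drop = FALSE])
    }
    cands[[length(cands) + 1L]] <- list(offset = ctr, n_inliers = sum(inl))
  }
  ns <- vapply(cands, `[[`, 0, "n_inliers")
  # corner geometry determines the shift only modulo the grid lattice;
  # return every strong candidate (typically the true shift plus aliases
  # one pitch apart) for image-content disambiguation
  strong <- which(ns >= max(3, 0.7 * max(ns)))
  dist2 <- vapply(strong, function(i) sum((cands[[i]]$offset - init)^2), 0)
  cands[strong[order(dist2)]]
}

# Pearson correlation of the overlapping content at a fixed integer-rounded
# offset; distinguishes lattice aliases because the major graduations of
# the scale break the single-pitch periodicity.  `offset` is a theoretical
# (undistorted) shift when `intr` is given, so the window in B is placed
# at the locally distorted displacement of the window centre.
.score_offset <- function(imgA, imgB, offset, intr = NULL, win = 256L) {
  o0 <- round(offset)
  h <- nrow(imgA); w <- ncol(imgA)
  cx0 <- max(0, -o0[1]); cx1 <- min(w, w - o0[1])
  cy0 <- max(0, -o0[2]); cy1 <- min(h, h - o0[2])
  if (cx1 - cx0 < 16 || cy1 - cy0 < 16) return(-Inf)
  half_x <- min(win %/% 2, floor((cx1 - cx0) / 2) - 1)
  half_y <- min(win %/% 2, floor((cy1 - cy0) / 2) - 1)
  ccx <- floor((cx0 + cx1) / 2); ccy <- floor((cy0 + cy1) / 2)
  local_search <- 0L
  if (!is.null(intr)) {
    pB <- tryCatch(
      distort_point(undistort_point(c(ccx, ccy), intr) + offset, intr),
      error = function(e) c(ccx, ccy) + offset)
    o0 <- round(pB - c(ccx, ccy))
  } else {
    # without intrinsics the local distorted shift can differ from the
    # candidate by a few px; take the best correlation in a small box
    local_search <- 3L
  }
  ax <- (ccx - half_x):(ccx + half_x); ay <- (ccy - half_y):(ccy + half_y)
  ax <- ax[seq(1, length(ax), by = 2)]; ay <- ay[seq(1, length(ay), by = 2)]
  a <- as.numeric(imgA[ay + 1, ax + 1])
  best <- -Inf
  for (ddx in -local_search:local_search) for (ddy in -local_search:local_search) {
    bx <- ax + o0[1] + ddx; by <- ay + o0[2] + ddy
    if (min(bx) < 0 || max(bx) > w - 1 || min(by) < 0 || max(by) > h - 1) next
    v <- suppressWarnings(stats::cor(a, as.numeric(imgB[by + 1, bx + 1])))
    if (is.finite(v) && v > best) best <- v
  }
  best
}

# shift-aware windowed cross-correlation: resolve the bulk of `init` by
# cropping matching windows out of the overlap region, then measure the
# small residual shift between the crops (keeps FFTs small even for
# half-frame offsets)
.xcorr_offset_crop <- function(imgA, imgB, init, search, crop = 384L) {
  o0 <- round(init)
  h <- nrow(imgA); w <- ncol(imgA)
  # overlap of A's content still visible in B (0-based pixel ranges)
  cx0 <- max(0, -o0[1]); cx1 <- min(w, w - o0[1])
  cy0 <- max(0, -o0[2]); cy1 <- min(h, h - o0[2])
  if (cx1 - cx0 < 64 || cy1 - cy0 < 64)
    return(.xcorr_offset(imgA, imgB, init, search))
  half_x <- min(crop %/% 2, floor((cx1 - cx0) / 2) - 1)
  half_y <- min(crop %/% 2, floor((cy1 - cy0) / 2) - 1)
  ccx <- floor((cx0 + cx1) / 2); ccy <- floor((cy0 + cy1) / 2)
  ax <- (ccx - half_x):(ccx + half_x - 1); ay <- (ccy - half_y):(ccy + half_y - 1)
  bx <- ax + o0[1]; by <- ay + o0[2]
  res <- .xcorr_offset(imgA[ay + 1, ax + 1], imgB[by + 1, bx + 1],
                       init - o0, search)
  res$offset <- res$offset + o0
  res
}

.xcorr_offset <- function(imgA, imgB, init, search) {
  A <- .norm_img(imgA); B <- .norm_img(imgB)
  A <- A - mean(A); B <- B - mean(B)
  h <- nrow(A); w <- ncol(A)
  H2 <- stats::nextn(2 * h, c(2, 3, 5)); W2 <- stats::nextn(2 * w, c(2, 3, 5))
  A0 <- matrix(0, H2, W2); B0 <- matrix(0, H2, W2)
  A0[1:h, 1:w] <- A; B0[1:h, 1:w] <- B
  C <- Re(stats::fft(stats::fft(B0) * Conj(stats::fft(A0)), inverse = TRUE))
  # lag grids (fftshift-free): index i -> lag (i-1) mapped into (-N/2, N/2]
  lag_r <- ((seq_len(H2) - 1 + H2 %/% 2) %% H2) - H2 %/% 2
  lag_c <- ((seq_len(W2) - 1 + W2 %/% 2) %% W2) - W2 %/% 2
  ok_r <- abs(lag_r - init[2]) <= search
  ok_c <- abs(lag_c - init[1]) <= search
  Cm <- C
  Cm[!ok_r, ] <- -Inf; Cm[, !ok_c] <- -Inf
  pk <- arrayInd(which.max(Cm), dim(Cm))
  pr <- pk[1]; pc <- pk[2]
  subpix <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dr <- subpix(C[wrap(pr - 1, H2), pc], C[pr, pc], C[wrap(pr + 1, H2), pc])
  dc <- subpix(C[pr, wrap(pc - 1, W2)], C[pr, pc], C[pr, wrap(pc + 1, W2)])
  list(offset = c(lag_c[pc] + dc, lag_r[pr] + dr), peak = C[pr, pc])
}

#' Estimate the translation between two overlapping frames
#'
#' Returns the offset `(dx, dy)` in pixels by which the content of `imgB`
#' is displaced relative to `imgA` (a feature at `(u, v)` in A sits at
#' `(u + dx, v + dy)` in B).
#'
#' @param imgA,imgB Rasters of identical size.
#' @param method `"auto"` (corner features, cross-checked against the
#'   cross-correlation backend), `"corner"`, or `"xcorr"`.
#' @param init Expected offset `c(dx, dy)` in px (e.g. the commanded stage
#'   step converted to pixels); `NULL` means no prior.
#' @param search Half-width of the search window around `init` (px).
#' @param intr Optional [intrinsic_params()]; corner coordinates are
#'   undistorted before matching.
#' @param min_inliers Fewer corner inliers than this triggers the
#'   cross-correlation fallback.
#' @param cornersA,cornersB Optional precomputed corner matrices (from
#'   series drivers that extract each frame once).
#' @return Object of class `stitch_result`: list with `dx`, `dy`,
#'   `n_inliers`, `method`, and `theta_deg` (`atan(dy/dx)` in degrees when
#'   `dx != 0`, else `NA`).
#' @export
estimate_offset <- function(imgA, imgB, method = c("auto", "corner", "xcorr"),
                            init = NULL, search = NULL, intr = NULL,
                            min_inliers = 8L, cornersA = NULL, cornersB = NULL) {
  method <- match.arg(method)
  stopifnot(all(dim(imgA) == dim(imgB)))
  if (is.null(init)) init <- c(0, 0)
  if (is.null(search)) search <- max(dim(imgA))
  res <- NULL
  cA <- cornersA
  if (method %in% c("auto", "corner")) {
    cr <- tryCatch({
      cA <- if (is.null(cornersA)) .grid_corners(imgA, intr) else cornersA
      cB <- if (is.null(cornersB)) .grid_corners(imgB, intr) else cornersB
      cands <- .corner_offset(cA, cB, init, search)
      if (length(cands) > 1L) {
        sc <- vapply(cands, function(cc)
          .score_offset(imgA, imgB, cc$offset, intr = intr), 0)
        cands[[which.max(sc)]]
      } else if (length(cands)) cands[[1L]] else NULL
    }, error = function(e) NULL)
    if (!is.null(cr) && cr$n_inliers >= min_inliers) {
      res <- list(dx = cr$offset[1], dy = cr$offset[2],
                  n_inliers = cr$n_inliers, method = "corner")
      if (method == "auto") {
        pitch <- stats::median(diff(sort(unique(round(cA[, 1])))))
        period <- if (is.finite(pitch) && pitch > 4) pitch else 50
        xc <- .xcorr_offset_crop(imgA, imgB, init = cr$offset,
                                 search = 0.9 * period)
        if (max(abs(xc$offset - cr$offset)) > period / 2)
          stop("ambiguous registration: corner and cross-correlation ",
               "backends disagree by more than half a grid period (",
               sprintf("(%.2f, %.2f) vs (%.2f, %.2f) px", res$dx, res$dy,
                       xc$offset[1], xc$offset[2]), ")")
      }
    } else if (method == "corner") {
      stop("registration error: ",
           if (is.null(cr)) "corner extraction failed"
           else sprintf("only %d corner inliers (need %d)",
                        cr$n_inliers, min_inliers))
    }
  }
  if (is.null(res)) {
    xc <- if (max(abs(init)) > 50)
      .xcorr_offset_crop(imgA, imgB, init, search)
    else .xcorr_offset(imgA, imgB, init, search)
    res <- list(dx = xc$offset[1], dy = xc$offset[2],
                n_inliers = 0L, method = "xcorr")
  }
  res$theta_deg <- if (res$dx != 0) atan(res$dy / res$dx) * 180 / pi else NA_real_
  structure(res, class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf("Stitch offset: dx = %.3f px, dy = %.3f px (%s, %d inliers)\n",
              x$dx, x$dy, x$method, x$n_inliers))
  invisible(x)
}

#' Camera deflection angle from a stitching offset
#'
#' For frames taken across an X-direction stage step the mounting angle is
#' `theta = arctan(dy / dx)`; for a Y-direction step the roles transpose
#' (`theta = arctan(-dx / dy)`), so both series estimate the same angle
#' under the package's v-down image convention.
#'
#' @param dx,dy Stitching offset (px).
#' @param axis Direction of the stage step the pair spans.
#' @return Deflection angle in degrees.
#' @export
deflection_angle <- function(dx, dy, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") {
    if (dx == 0) stop("undefined deflection angle: dx = 0 for an X-step pair")
    atan(dy / dx) * 180 / pi
  } else {
    if (dy == 0) stop("undefined deflection angle: dy = 0 for a Y-step pair")
    atan(-dx / dy) * 180 / pi
  }
}

#' Average deflection angle over stitched pairs
#'
#' Arithmetic mean of the per-pair angles (mean of angles, not the angle
#' of the summed offsets).
#'
#' @param results List of `stitch_result` objects (or a numeric vector of
#'   per-pair angles in degrees).
#' @return Mean deflection angle (degrees).
#' @export
average_deflection <- function(results) {
  if (is.numeric(results)) th <- results
  else th <- vapply(results, function(r) r$theta_deg, 0)
  if (!length(th)) stop("no stitch results to average")
  if (anyNA(th)) stop("stitch results without a defined angle")
  mean(th)
}

#' Estimate the deflection angle from a displacement series
#'
#' Registers each consecutive pair of a stepped series and averages the
#' per-pair deflection angles, using the commanded step as the search
#' prior.
#'
#' @param frames List of rasters (ordered along the series).
#' @param plan The [displacement_plan()] the series was taken under.
#' @param px_per_um_nominal Nominal pixel scale (px/µm) for the prior.
#' @param intr Optional [intrinsic_params()] for corner undistortion.
#' @param search Search half-width around the nominal offset (px); the
#'   default admits mounting angles up to about 8 degrees.
#' @return List with `pairs` (data.frame: group, dx, dy, theta_deg) and
#'   `theta_deg` (the average), printed like a per-pair stitching table.
#' @export
deflection_from_series <- function(frames, plan, px_per_um_nominal = 1,
                                   intr = NULL, search = NULL,
                                   corners = NULL) {
  stopifnot(length(frames) >= 2)
  step_px <- plan$direction * plan$step_um * px_per_um_nominal
  if (is.null(search)) search <- max(60, 0.15 * abs(step_px))
  init <- if (plan$axis == "x") c(step_px, 0) else c(0, step_px)
  n <- length(frames) - 1L
  if (is.null(corners))
    corners <- lapply(frames, function(f)
      tryCatch(.grid_corners(f, intr), error = function(e) NULL))
  tab <- data.frame(group = seq_len(n), dx = NA_real_, dy = NA_real_,
                    theta_deg = NA_real_)
  for (i in seq_len(n)) {
    o <- estimate_offset(frames[[i]], frames[[i + 1]], init = init,
                         search = search, intr = intr,
                         cornersA = corners[[i]], cornersB = corners[[i + 1]])
    # orient along the positive axis so theta's sign is direction-free
    s <- plan$direction
    tab$dx[i] <- s * o$dx; tab$dy[i] <- s * o$dy
    tab$theta_deg[i] <- deflection_angle(s * o$dx, s * o$dy, axis = plan$axis)
  }
  list(pairs = tab, theta_deg = mean(tab$theta_deg))
}
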
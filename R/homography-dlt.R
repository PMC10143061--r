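# Direct linear transform estimation of the plane-to-image homography from
# point pairs and line pairs, and its decomposition into magnification,
# pose and distortion-compensation offsets.

#' Point and line correspondences for homography estimation
#'
#' The map is taken world-to-image throughout: image points satisfy
#' `p ~ H P` and world lines satisfy `L ~ t(H) l`.
#'
#' @param world_pts,image_pts n x 2 matrices of matching points (world in
#'   µm on the stage plane, image in px); n >= 4 unless enough line pairs
#'   are supplied (each pair of either kind contributes two constraints,
#'   eight are required).
#' @param world_lines,image_lines Optional m x 3 matrices of matching lines
#'   in homogeneous coordinates `(a, b, c)` with `a x + b y + c = 0`.
#' @return An object of class `correspondences`.
#' @export
correspondences <- function(world_pts = NULL, image_pts = NULL,
                            world_lines = NULL, image_lines = NULL) {
  np <- if (is.null(world_pts)) 0L else nrow(world_pts)
  nl <- if (is.null(world_lines)) 0L else nrow(world_lines)
  if (np) stopifnot(ncol(world_pts) == 2, all(dim(image_pts) == dim(world_pts)))
  if (nl) stopifnot(ncol(world_lines) == 3, all(dim(image_lines) == dim(world_lines)))
  if (2L * (np + nl) < 8L)
    stop("need at least 8 constraints (point pairs + line pairs >= 4)")
  structure(list(world_pts = world_pts, image_pts = image_pts,
                 world_lines = world_lines, image_lines = image_lines),
            class = "correspondences")
}

# Hartley-style similarity normalization from a point cloud
.norm_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  s <- sqrt(2) / mean(sqrt(rowSums(d^2)))
  if (!is.finite(s) || s <= 0) s <- 1
  matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Estimate the homography by DLT over points and lines
#'
#' Stacks the cross-product incidence constraints `p x (H P) = 0` for each
#' point pair and `L x (t(H) l) = 0` for each line pair into a homogeneous
#' linear system in the nine entries of `H`, solved by singular value
#' decomposition (right singular vector of the smallest singular value).
#' Point coordinates are similarity-normalized first for conditioning.
#'
#' @param c A [correspondences()] object.
#' @return A [homography()] (world to image).
#' @export
estimate_homography <- function(c) {
  stopifnot(inherits(c, "correspondences"))
  Tw <- if (!is.null(c$world_pts)) .norm_transform(c$world_pts) else diag(3)
  Ti <- if (!is.null(c$image_pts)) .norm_transform(c$image_pts) else diag(3)
  rows <- list()
  if (!is.null(c$world_pts)) {
    for (i in seq_len(nrow(c$world_pts))) {
      P <- Tw %*% c(c$world_pts[i, ], 1)
      p <- Ti %*% c(c$image_pts[i, ], 1)
      # rows of p x (H P) = 0; coefficient of H[r, c] is p-cross terms * P[c]
      Z <- rep(0, 3)
      rows[[length(rows) + 1L]] <- rbind(
        c(Z, -p[3] * P, p[2] * P),
        c(p[3] * P, Z, -p[1] * P),
        c(-p[2] * P, p[1] * P, Z))
    }
  }
  if (!is.null(c$world_lines)) {
    Twi <- t(solve(Tw)); Tii <- t(solve(Ti))
    for (i in seq_len(nrow(c$world_lines))) {
      L <- Twi %*% c$world_lines[i, ]
      l <- as.numeric(Tii %*% c$image_lines[i, ])
      # m = t(H) l has m[c] = sum_r H[r, c] l[r]; rows of L x m = 0
      cof <- function(cc) { out <- matrix(0, 3, 3); out[, cc] <- l; as.numeric(t(out)) }
      rows[[length(rows) + 1L]] <- rbind(
        L[2] * cof(3) - L[3] * cof(2),
        L[3] * cof(1) - L[1] * cof(3),
        L[1] * cof(2) - L[2] * cof(1))
    }
  }
  A <- do.call(rbind, rows)
  sv <- svd(A, nu = 0, nv = 9)
  d <- sv$d
  if (d[8] / d[1] < 1e-10)
    stop("degenerate geometry: correspondences do not determine a homography ",
         "(second-smallest singular value ratio ", format(d[8] / d[1]), ")")
  if (d[9] / d[8] > 0.1)
    stop("ill-conditioned geometry: smallest/second-smallest singular value ",
         "ratio ", format(d[9] / d[8]), " exceeds 0.1")
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  homography(solve(Ti) %*% Hn %*% Tw)
}

#' Focal scales from a homography with known principal point
#'
#' With zero skew and a near-fronto-parallel stage plane, the upper 2x2
#' block of the centred homography is `diag(fx, fy) %*% R2`, so the row
#' norms give the focal scales (px/µm) independent of the in-plane
#' rotation.
#'
#' @param H A [homography()] (world µm to image px).
#' @param u0,v0 Principal point (px).
#' @return `c(fx, fy)` in px/µm.
#' @export
focal_from_homography <- function(H, u0, v0) {
  Hn <- unclass(H) / H[3, 3]
  B <- rbind(Hn[1, ] - u0 * Hn[3, ], Hn[2, ] - v0 * Hn[3, ])
  c(fx = sqrt(sum(B[1, 1:2]^2)), fy = sqrt(sum(B[2, 1:2]^2)))
}

#' Decompose the imaging homography into pose and magnification
#'
#' Computes `[r1 r2 t] = lambda * solve(A) %*% H` with `lambda` chosen so
#' `|r1| = 1` (sign so that `t[3] >= 0`), completes `r3 = r1 x r2`,
#' projects to the nearest rotation, and derives the corrected translation
#' `t_hat = Lu * t / lambda`, the per-axis magnifications
#' `Mu = fx * Lu`, `Mv = fy * Lv`, their mean `M`, the magnification ratio
#' `M' = M / M_nominal`, and the distortion-compensation offsets
#' `(delta_x, delta_y)` as the first two components of `R %*% t_hat`.
#'
#' @param H A [homography()].
#' @param intr [intrinsic_params()] with resolved focal scales.
#' @param Lu,Lv Physical camera pixel side lengths (µm/pixel).
#' @param M_nominal Rated objective magnification.
#' @return List with `pose` ([extrinsic_pose()]), `mag` (list `Mu, Mv, M,
#'   Lu, Lv, M_nominal, M_prime`) and `delta` (`c(delta_x, delta_y)`, µm).
#' @export
decompose_imaging <- function(H, intr, Lu = 20, Lv = 20, M_nominal = 20) {
  A <- intrinsic_matrix(intr)
  B <- solve(A, unclass(H))
  lambda <- 1 / sqrt(sum(B[, 1]^2))
  if ((lambda * B[3, 3]) < 0) lambda <- -lambda
  r1 <- lambda * B[, 1]; r2 <- lambda * B[, 2]; t <- lambda * B[, 3]
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R0 <- cbind(r1, r2, r3)
  sv <- svd(R0)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  t_hat <- Lu * t / lambda
  Mu <- intr$fx * Lu; Mv <- intr$fy * Lv
  M <- (Mu + Mv) / 2
  delta <- as.numeric(R %*% t_hat)[1:2]
  list(pose = extrinsic_pose(R = R, t = t, t_hat = t_hat),
       mag = list(Mu = Mu, Mv = Mv, M = M, Lu = Lu, Lv = Lv,
                  M_nominal = M_nominal, M_prime = M / M_nominal),
       delta = c(delta_x = delta[1], delta_y = delta[2]))
}

#' Build grid correspondences from a distortion fit
#'
#' Pairs the fitted (undistortion-corrected) centerlines with the known
#' grid geometry: each family is index-assigned to world grid lines by its
#' position at the image centre under the nominal pixel scale (centred on
#' the middle visible line, which is all a partially visible grid
#' determines), and the pairwise intersections of the corrected lines give
#' the point pairs.
#'
#' @param fit A `distortion_fit`.
#' @param spec A [grid_spec()].
#' @param px_per_um_nominal Nominal pixel scale (px/µm) used only for
#'   index assignment.
#' @param max_pts Cap on the number of point pairs (subsampled evenly).
#' @return A [correspondences()] object.
#' @export
grid_correspondences <- function(fit, spec = grid_spec(),
                                 px_per_um_nominal = 1, max_pts = 200L) {
  stopifnot(inherits(fit, "distortion_fit"))
  iv <- which(fit$orientation == "vertical")
  ih <- which(fit$orientation == "horizontal")
  if (length(iv) < 2 || length(ih) < 2)
    stop("need at least two corrected lines per family")
  w <- fit$image_size[1]; h <- fit$image_size[2]
  pos_of <- function(i) {
    at <- if (fit$orientation[i] == "vertical") (h - 1) / 2 else (w - 1) / 2
    ca <- cos(fit$alpha[i]); sa <- sin(fit$alpha[i])
    if (fit$orientation[i] == "vertical") -(fit$phi[i] + at * sa) / ca
    else -(fit$phi[i] + at * ca) / sa
  }
  assign_world <- function(ii) {
    pos <- vapply(ii, pos_of, 0)
    ii <- ii[order(pos)]; pos <- sort(pos)
    mid <- pos[ceiling(length(pos) / 2)]
    idx <- round((pos - mid) / (spec$pitch_um * px_per_um_nominal))
    if (anyDuplicated(idx))
      stop("grid line index assignment is ambiguous at this pixel scale")
    list(ii = ii, world = idx * spec$pitch_um)
  }
  av <- assign_world(iv); ah <- assign_world(ih)
  # world lines: vertical X = x0 -> (1, 0, -x0); horizontal Y = y0 -> (0, 1, -y0)
  wl <- rbind(cbind(1, 0, -av$world), cbind(0, 1, -ah$world))
  il <- rbind(
    t(vapply(av$ii, function(i) c(cos(fit$alpha[i]), sin(fit$alpha[i]), fit$phi[i]), numeric(3))),
    t(vapply(ah$ii, function(i) c(cos(fit$alpha[i]), sin(fit$alpha[i]), fit$phi[i]), numeric(3))))
  # point pairs: intersections of corrected image lines <-> grid nodes
  wp <- NULL; ip <- NULL
  for (a in seq_along(av$ii)) for (b in seq_along(ah$ii)) {
    i <- av$ii[a]; j <- ah$ii[b]
    Mm <- rbind(c(cos(fit$alpha[i]), sin(fit$alpha[i])),
                c(cos(fit$alpha[j]), sin(fit$alpha[j])))
    rhs <- -c(fit$phi[i], fit$phi[j])
    p <- solve(Mm, rhs)
    if (p[1] < -0.5 || p[1] > w - 0.5 || p[2] < -0.5 || p[2] > h - 0.5) next
    wp <- rbind(wp, c(av$world[a], ah$world[b]))
    ip <- rbind(ip, p)
  }
  if (!is.null(wp) && nrow(wp) > max_pts) {
    sel <- unique(round(seq(1, nrow(wp), length.out = max_pts)))
    wp <- wp[sel, , drop = FALSE]; ip <- ip[sel, , drop = FALSE]
  }
  correspondences(world_pts = wp, image_pts = ip,
                  world_lines = wl, image_lines = il)
}
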
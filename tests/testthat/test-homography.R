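# build exact correspondences (points + lines) from a known H (world->image)
h_correspondences <- function(H, n_pts = 6, n_lines = 6, seed = 1) {
  set.seed(seed)
  W <- cbind(runif(n_pts, -400, 400), runif(n_pts, -400, 400))
  Pw <- cbind(W, 1)
  Pi <- t(apply(Pw, 1, function(p) { q <- H %*% p; q[1:2] / q[3] }))
  # world lines through random point pairs; image lines via inv(t(H))
  wl <- t(replicate(n_lines, {
    a <- c(runif(1, -400, 400), runif(1, -400, 400), 1)
    b <- c(runif(1, -400, 400), runif(1, -400, 400), 1)
    l <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    l / sqrt(sum(l[1:2]^2))
  }))
  il <- t(apply(wl, 1, function(L) {
    l <- solve(t(H), L)
    l / sqrt(sum(l[1:2]^2))
  }))
  correspondences(world_pts = W, image_pts = Pi,
                  world_lines = wl, image_lines = il)
}

test_that("DLT recovers the identity and a general fixed-seed homography", {
  ci <- h_correspondences(diag(3), seed = 2)
  Hi <- estimate_homography(ci)
  expect_lt(max(abs(unclass(Hi) - unclass(homography(diag(3))))), 1e-12)

  set.seed(99)
  Htrue <- matrix(c(1.02, -0.08, 310, 0.07, 0.98, 240, 1e-5, -2e-5, 1),
                  3, 3, byrow = TRUE)
  ch <- h_correspondences(Htrue, seed = 3)
  Hh <- estimate_homography(ch)
  expect_lt(max(abs(unclass(Hh) - unclass(homography(Htrue)))), 1e-9)
})

test_that("estimation is invariant to the homogeneous scale of the lines", {
  Htrue <- matrix(c(0.99, -0.1, 600, 0.1, 0.99, 450, 0, 0, 1),
                  3, 3, byrow = TRUE)
  cc <- h_correspondences(Htrue, seed = 4)
  set.seed(5)
  cc2 <- cc
  cc2$world_lines <- cc$world_lines * runif(nrow(cc$world_lines), 0.1, 9)
  cc2$image_lines <- cc$image_lines * runif(nrow(cc$image_lines), 0.1, 9)
  expect_equal(unclass(estimate_homography(cc2)),
               unclass(estimate_homography(cc)), tolerance = 1e-9)
})

test_that("collinear points are flagged as degenerate", {
  W <- cbind(seq(10, 40, 10), seq(10, 40, 10))
  cc <- correspondences(world_pts = W, image_pts = W)
  expect_error(estimate_homography(cc), "degenerate|ill-conditioned")
})

test_that("decomposition round-trips a known pose and magnification", {
  intr <- intrinsic_params(1, 1, 600, 450, 0)
  A <- intrinsic_matrix(intr)
  t_true <- c(-2.5, -2.7, 0.2)
  H <- homography(A %*% cbind(diag(3)[, 1:2], t_true))
  dec <- decompose_imaging(H, intr, Lu = 20, Lv = 20, M_nominal = 20)
  expect_equal(dec$pose$t, t_true, tolerance = 1e-9)
  expect_equal(dec$pose$R, diag(3), tolerance = 1e-9)
  # fx = fy = 1 px/um on a 20 um pixel is 20x magnification
  expect_equal(dec$mag$M, 20)
  expect_equal(dec$mag$M_prime, 1)
})

test_that("magnification ratio arithmetic matches the worked calibration", {
  intr <- intrinsic_params(19.843 / 20, 19.843 / 20, 600, 450, 0)
  A <- intrinsic_matrix(intr)
  H <- homography(A %*% cbind(diag(3)[, 1:2], c(0, 0, 1)))
  dec <- decompose_imaging(H, intr, Lu = 20, Lv = 20, M_nominal = 20)
  expect_equal(dec$mag$M, 19.843, tolerance = 1e-12)
  expect_equal(round(dec$mag$M_prime, 4), 0.9922)
})

test_that("focal scales are recovered regardless of in-plane rotation", {
  th <- -5.58 * pi / 180
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Hm <- rbind(c(0.993 * R2[1, ], 600), c(0.992 * R2[2, ], 450),
              c(0, 0, 1))
  ff <- focal_from_homography(homography(Hm), 600, 450)
  expect_equal(unname(ff), c(0.993, 0.992), tolerance = 1e-9)
})
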
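test_that("radial distortion correction matches hand-evaluated cases", {
  # at the principal point the correction vanishes for any k
  intr <- intrinsic_params(1, 1, 600.3, 450.2, 0.0122)
  expect_equal(undistort_point(c(600.3, 450.2), intr), c(600.3, 450.2))
  # zero factor leaves any point unchanged
  intr0 <- intrinsic_params(1, 1, 600, 450, 0)
  expect_equal(undistort_point(c(123.4, 567.8), intr0), c(123.4, 567.8))
  # hand evaluation: r^2 = 100, correction 1e-6 * 10 * 100 = 1e-3
  intr1 <- intrinsic_params(1, 1, 600, 450, 1e-6)
  expect_equal(undistort_point(c(610, 450), intr1), c(610.001, 450))
  expect_error(undistort_point(c(NaN, 1), intr1), "finite")
})

test_that("distortion inversion round-trips and handles edge cases", {
  intr <- intrinsic_params(1, 1, 600, 450, 1e-6)
  expect_equal(distort_point(c(610.001, 450), intr), c(610, 450),
               tolerance = 1e-9)
  expect_equal(distort_point(c(600, 450), intr), c(600, 450))
  intr0 <- intrinsic_params(1, 1, 600, 450, 0)
  expect_equal(distort_point(c(321, 123), intr0), c(321, 123))
})

test_that("undistort . distort is the identity within 1e-9 px across the field", {
  set.seed(42)
  for (k in c(-1e-7, -1e-8, 1e-8, 1e-7)) {
    intr <- intrinsic_params(1, 1, 600, 450, k)
    ang <- runif(40, 0, 2 * pi)
    rad <- runif(40, 0, 400)
    pts <- cbind(600 + rad * cos(ang), 450 + rad * sin(ang))
    back <- undistort_point(distort_point(pts, intr), intr)
    expect_lt(max(abs(back - pts)), 1e-9)
  }
})

test_that("the correction is radially symmetric about the principal point", {
  intr <- intrinsic_params(1, 1, 600, 450, 5e-8)
  set.seed(7)
  for (i in 1:20) {
    r <- runif(1, 10, 500); a <- runif(1, 0, 2 * pi); rot <- runif(1, 0, 2 * pi)
    p1 <- c(600 + r * cos(a), 450 + r * sin(a))
    p2 <- c(600 + r * cos(a + rot), 450 + r * sin(a + rot))
    c1 <- undistort_point(p1, intr) - p1
    c2 <- undistort_point(p2, intr) - p2
    # same magnitude, direction rotated with the offset vector
    expect_equal(sqrt(sum(c1^2)), sqrt(sum(c2^2)), tolerance = 1e-9)
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    expect_equal(as.numeric(R %*% c1), c2, tolerance = 1e-9)
  }
})

test_that("error transform assembles exactly as specified", {
  T0 <- compose_error_transform()
  expect_equal(unclass(T0), diag(3), ignore_attr = TRUE)
  # magnification + deflection only: off-diagonals are +/- sin(theta) * M'
  Tm <- compose_error_transform(M_prime = 0.9922,
                                deflection = deflection_params(-5.578))
  s <- sin(-5.578 * pi / 180)
  expect_equal(Tm[1, 2], -s * 0.9922)
  expect_equal(Tm[2, 1], s * 0.9922)
  expect_equal(Tm[1, 1], 0.9922)
  # displacement error lands in the third column
  Td <- compose_error_transform(axis = axis_errors(dxp = 0.01))
  expect_equal(Td[1, 3], 0.01)
  expect_equal(Td[2, 3], 0)
})

test_that("error transform is linear in the displacement errors", {
  defl <- deflection_params(-3)
  pose <- extrinsic_pose()
  tvals <- function(dx, dy)
    compose_error_transform(1.01, defl, axis_errors(dxp = dx, dyp = dy), pose)
  T1 <- tvals(0.01, 0.02); T2 <- tvals(0.03, -0.01); T0 <- tvals(0, 0)
  Tsum <- tvals(0.04, 0.01)
  expect_equal(T1 + T2 - T0, Tsum, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pose and parameter validation rejects bad inputs", {
  expect_error(intrinsic_params(fx = -1), "positive")
  expect_error(intrinsic_params(k = Inf), "finite")
  expect_error(axis_errors(dxp = 0.2), "implausible")
  expect_error(extrinsic_pose(R = diag(3) * 1.001), "orthonormal")
  R_reflect <- diag(c(1, 1, -1))
  expect_error(extrinsic_pose(R = R_reflect), "proper rotation")
  expect_error(deflection_params(50), "45")
})

test_that("homography wrapper normalizes and checks rank", {
  H <- homography(matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2), 3, 3))
  expect_equal(sqrt(sum(H^2)), 1)
  expect_gt(H[which.max(abs(H))], 0)
  expect_error(homography(matrix(1, 3, 3)), "rank")
})
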
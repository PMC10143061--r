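test_that("an exact integer shift is recovered exactly by cross-correlation", {
  set.seed(21)
  base <- matrix(runif(250 * 300), 250, 300)
  base <- base + 0.3 * sin(outer(1:250, 1:300, "+") / 7)  # some structure
  A <- matrix(0.5, 300, 360); B <- matrix(0.5, 300, 360)
  A[26:275, 31:330] <- base
  B[(26 - 5):(275 - 5), (31 + 17):(330 + 17)] <- base  # shift (dx=17, dy=-5)
  o <- estimate_offset(A, B, method = "xcorr")
  expect_equal(c(o$dx, o$dy), c(17, -5), tolerance = 1e-6)
  oid <- estimate_offset(A, A, method = "xcorr")
  expect_equal(c(oid$dx, oid$dy), c(0, 0), tolerance = 1e-6)
})

test_that("registration is antisymmetric on fixture pairs", {
  tr <- std_truth(noise_sigma = 1, seed = 8L)
  ser <- simulate_series(tr, grid_spec(n_squares = Inf),
                         displacement_plan("x", 1L, 1L, 600))
  A <- ser$frames[[1]]; B <- ser$frames[[2]]
  oab <- estimate_offset(A, B, init = c(600, 0), search = 90, intr = tr$intr)
  oba <- estimate_offset(B, A, init = c(-600, 0), search = 90, intr = tr$intr)
  expect_lt(abs(oab$dx + oba$dx), 0.2)
  expect_lt(abs(oab$dy + oba$dy), 0.2)
})

test_that("deflection angle follows the printed stitching table", {
  tab <- table2_pairs()
  th <- mapply(deflection_angle, tab$dx, tab$dy)
  expect_equal(round(th, 3), tab$theta)
  # the published average is the mean of the 3-decimal per-pair angles
  expect_equal(round(average_deflection(round(th, 3)), 3), -5.578)
})

test_that("deflection angle edge cases and symmetries hold", {
  expect_equal(deflection_angle(123, 0), 0)
  expect_error(deflection_angle(0, 10), "undefined")
  expect_error(deflection_angle(10, 0, axis = "y"), "undefined")
  for (dx in c(50, 304, 1000)) for (dy in c(-30, 4, 17))
    expect_identical(deflection_angle(dx, -dy), -deflection_angle(dx, dy))
  # a Y-direction pair measures the same mounting angle
  th <- -4.3 * pi / 180
  d <- 500 * c(-sin(th), cos(th))  # offset of a +Y step under rotation th
  expect_equal(deflection_angle(d[1], d[2], axis = "y"), -4.3,
               tolerance = 1e-9)
})

test_that("averaging deflection angles is the arithmetic mean of angles", {
  r1 <- structure(list(theta_deg = 2), class = "stitch_result")
  r2 <- structure(list(theta_deg = -2), class = "stitch_result")
  expect_equal(average_deflection(list(r1, r2)), 0)
  expect_equal(average_deflection(list(r1)), 2)
  expect_error(average_deflection(list()), "no stitch")
})

test_that("series deflection recovers the injected mounting angle", {
  tr <- std_truth(theta_deg = 3.7, seed = 5L)
  ser <- simulate_series(tr, grid_spec(n_squares = Inf),
                         displacement_plan("x", 1L, 5L, 600))
  d <- deflection_from_series(ser$frames, ser$plan, 1, intr = tr$intr)
  expect_lt(abs(d$theta_deg - 3.7), 0.05)
  expect_equal(nrow(d$pairs), 5)
})

test_that("ambiguous offsets fall back or flag rather than silently alias", {
  # no prior and an offset beyond half a period: corner consensus plus
  # content scoring must still land on the physical shift
  tr <- std_truth(theta_deg = -5.58, seed = 9L)
  ser <- simulate_series(tr, grid_spec(n_squares = Inf),
                         displacement_plan("x", 1L, 1L, 600))
  o <- estimate_offset(ser$frames[[1]], ser$frames[[2]],
                       init = c(600, 0), search = 90, intr = tr$intr)
  expect_equal(o$dx,
               600 * px_per_um(tr) * (1 + tr$axis$dxp) * cos(-5.58 * pi / 180),
               tolerance = 1e-3)
  expect_equal(o$method, "corner")
  expect_gte(o$n_inliers, 8)
})
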
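test_that("axis means over the printed per-group offsets are reproduced", {
  off <- table3_offsets()
  means <- vapply(off, function(o)
    axis_error_from_offsets(o, 600, 1)$raw_px, 0)
  expect_equal(unname(means), c(-5.2, -5.8, -5.7, -5.2))
  # relative errors at 1 px/um and 600 um steps
  expect_equal(axis_error_from_offsets(off$dxp, 600, 1)$delta_rel, -5.2 / 600)
})

test_that("axis error is exactly the arithmetic mean of pairwise errors", {
  set.seed(31)
  for (i in 1:10) {
    e <- rnorm(sample(3:12, 1), -5, 2)
    acc <- 0; for (x in e) acc <- acc + x  # brute-force oracle
    expect_equal(axis_error_from_offsets(e, 600, 1)$raw_px, acc / length(e))
  }
  expect_equal(axis_error_from_offsets(rep(0, 5), 600, 1)$delta_rel, 0)
})

test_that("series estimation recovers the injected relative error", {
  tr <- std_truth(seed = 6L)  # dxp = -5.2/600 ~ -0.00867
  ser <- simulate_series(tr, grid_spec(n_squares = Inf),
                         displacement_plan("x", 1L, 6L, 600))
  ae <- axis_error_from_series(ser$frames, ser$plan, px_per_um = px_per_um(tr),
                               theta_deg = tr$theta_deg, intr = tr$intr)
  expect_equal(ae$delta_rel, tr$axis$dxp, tolerance = 0.05)
  # negative direction estimates the negative-direction error
  sern <- simulate_series(tr, grid_spec(n_squares = Inf),
                          displacement_plan("x", -1L, 6L, 600))
  aen <- axis_error_from_series(sern$frames, sern$plan,
                                px_per_um = px_per_um(tr),
                                theta_deg = tr$theta_deg, intr = tr$intr)
  expect_equal(aen$delta_rel, tr$axis$dxm, tolerance = 0.05)
})

test_that("quadrant coefficient evaluates the printed form", {
  ax0 <- axis_errors()
  expect_equal(mu(0, ax0, "scalar"), 1)
  ax <- axis_errors(dxp = 0.01, dyp = 0.01)
  expect_equal(mu(45, ax, "scalar"), 1.01 * sqrt(2), tolerance = 1e-12)
  expect_equal(unname(mu(45, ax, "per_axis")), c(1.01, 1.01))
  expect_equal(unname(mu(0, ax0, "per_axis")), c(1, 1))
})

test_that("quadrant selection follows the half-open convention", {
  ax <- axis_errors(dxp = 0.01, dxm = -0.02, dyp = 0.03, dym = -0.04)
  pick <- function(b) unname(mu(b, ax, "per_axis")) - 1
  expect_equal(pick(0), c(0.01, 0.03))      # Q1 includes 0
  expect_equal(pick(89.999), c(0.01, 0.03))
  expect_equal(pick(90), c(-0.02, 0.03))    # 90 falls in Q2
  expect_equal(pick(180), c(-0.02, -0.04))
  expect_equal(pick(270), c(0.01, -0.04))
  expect_equal(pick(359.999), c(0.01, -0.04))
  # property over a grid: x-error sign switches at 90/270, y at 180
  for (b in seq(1, 359, by = 7)) {
    sel <- pick(b)
    expect_equal(sel[1], if (b < 90 || b >= 270) 0.01 else -0.02)
    expect_equal(sel[2], if (b < 180) 0.03 else -0.04)
  }
})

test_that("scalar coefficient is continuous within quadrants with bounded jumps", {
  ax <- axis_errors(dxp = 0.01, dxm = -0.02, dyp = 0.03, dym = -0.04)
  bound <- abs(ax$dxp - ax$dxm) + abs(ax$dyp - ax$dym)
  for (q_edge in c(90, 180, 270)) {
    lo <- mu(q_edge - 1e-9, ax, "scalar")
    hi <- mu(q_edge, ax, "scalar")
    expect_lt(abs(hi - lo), bound + 1e-6)
  }
  # within-quadrant continuity
  b <- seq(10, 80, by = 0.5)
  v <- vapply(b, mu, 0, axis = ax, mode = "scalar")
  expect_lt(max(abs(diff(v))), 0.02)
})
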
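test_that("default grid render matches the declared raster geometry", {
  img <- std_grid_img()
  expect_equal(dim(img), c(900, 1200))
  expect_true(all(img >= 0 & img <= 255))
  # dark lines on a bright background
  expect_gt(stats::median(img), 150)
  expect_lt(min(img), 80)
})

test_that("rendering is deterministic for a fixed seed", {
  tr <- std_truth(noise_sigma = 3, seed = 11L)
  a <- render_grid_image(tr, grid_spec(), c(5, -3), frame = 2L)
  b <- render_grid_image(tr, grid_spec(), c(5, -3), frame = 2L)
  expect_identical(a, b)
  tr2 <- std_truth(noise_sigma = 3, seed = 12L)
  expect_false(identical(a, render_grid_image(tr2, grid_spec(), c(5, -3),
                                              frame = 2L)))
})

test_that("an untilted undistorted grid renders axis-parallel centerlines", {
  tr <- std_truth(k = 0, theta_deg = 0)
  img <- render_grid_image(tr, grid_spec(), c(0, 0))
  cl <- extract_center_lines(img)
  expect_lt(abs(family_tilt(cl, "vertical")), 0.02)
  expect_lt(abs(family_tilt(cl, "horizontal")), 0.02)
  rms <- vapply(c(cl$vertical, cl$horizontal), function(l) l$rms, 0)
  expect_lt(max(rms), 0.05)
})

test_that("a tilted grid renders lines at the injected angle", {
  tr <- std_truth(k = 0, theta_deg = -5.5)
  img <- render_grid_image(tr, grid_spec(), c(0, 0))
  cl <- extract_center_lines(img)
  expect_equal(family_tilt(cl, "vertical"), -5.5, tolerance = 0.02 / 5.5)
  expect_equal(family_tilt(cl, "horizontal"), -5.5, tolerance = 0.02 / 5.5)
})

test_that("stage model applies signed per-axis relative errors", {
  tr0 <- std_truth(axis = axis_errors())
  expect_equal(forward_stage_model(tr0, c(123, -45)), c(123, -45))
  tr <- std_truth(axis = axis_errors(dxp = -0.0087, dxm = -0.002))
  expect_equal(forward_stage_model(tr, c(100, 0)), c(99.13, 0))
  # negative motion selects the negative-direction error
  expect_equal(forward_stage_model(tr, c(-100, 0)), c(-99.8, 0))
})

test_that("series length and commanded positions follow the plan", {
  tr <- std_truth(axis = axis_errors(dxp = -0.01))
  ser <- simulate_series(tr, grid_spec(n_squares = Inf),
                         displacement_plan("x", 1L, 3L, 600))
  expect_length(ser$frames, 4)
  expect_equal(ser$commanded[, 1], c(0, 600, 1200, 1800))
  expect_equal(ser$actual[, 1], c(0, 594, 1188, 1782))
})

test_that("recovered offset of a zero-error series equals the pixel-scale step", {
  tr <- std_truth(k = 0, theta_deg = 0, M_true = 20, axis = axis_errors())
  ser <- simulate_series(tr, grid_spec(n_squares = Inf),
                         displacement_plan("x", 1L, 1L, 600))
  o <- estimate_offset(ser$frames[[1]], ser$frames[[2]],
                       init = c(600 * px_per_um(tr), 0), search = 60)
  expect_equal(o$dx, 600 * px_per_um(tr), tolerance = 0.1 / 600)
  expect_lt(abs(o$dy), 0.1)
})

test_that("a mechanical error shortens the measured inter-frame offset", {
  tr <- std_truth(k = 0, theta_deg = 0, M_true = 20,
                  axis = axis_errors(dxp = -0.01))
  ser <- simulate_series(tr, grid_spec(n_squares = Inf),
                         displacement_plan("x", 1L, 1L, 600))
  o <- estimate_offset(ser$frames[[1]], ser$frames[[2]],
                       init = c(600, 0), search = 40)
  expect_equal(o$dx, 594, tolerance = 0.1 / 594)  # 6 um-equivalent deficit
})

test_that("an oversized grid is rejected", {
  tr <- std_truth()
  expect_error(render_grid_image(tr, grid_spec(n_squares = 200, pitch_um = 50)),
               "fit")
})

test_that("series sidecar and rasters round-trip to disk", {
  tr <- std_truth(noise_sigma = 1, seed = 3L)
  ser <- simulate_series(tr, grid_spec(n_squares = Inf,
                                       image_w = 300, image_h = 200),
                         displacement_plan("x", 1L, 1L, 100))
  dir <- withr::local_tempdir()
  paths <- write_series(ser, tr, dir, format = "tiff")
  expect_true(all(file.exists(paths)))
  back <- read_raster(paths[1])
  expect_equal(back * 255, ser$frames[[1]], tolerance = 1e-6)
  side <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  expect_equal(side$theta_deg, tr$theta_deg)
  expect_equal(side$axis$dxp, tr$axis$dxp)
})
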
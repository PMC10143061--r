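test_that("the identity model forwards commands unchanged", {
  m <- identity_model()
  for (d in list(c(100, 0), c(0, 100), c(-100, 0), c(0, -100), c(70, -30)))
    expect_equal(compensate_move(m, d)$command, d, tolerance = 1e-12)
})

test_that("pure deflection compensation is the inverse rotation", {
  m <- build_compensation_model(list(M_prime = 1, delta_x = 0, delta_y = 0),
                                theta_deg = -5.578, axis = axis_errors(),
                                intr = intrinsic_params())
  cmd <- compensate_move(m, c(100, 0))$command
  a <- 5.578 * pi / 180  # rotate(+5.578 deg) applied to (100, 0)
  expect_equal(cmd, c(100 * cos(a), 100 * sin(a)), tolerance = 1e-12)
})

test_that("pure mechanical compensation inversely scales the command", {
  m <- build_compensation_model(list(M_prime = 1, delta_x = 0, delta_y = 0),
                                theta_deg = 0,
                                axis = axis_errors(dxp = -0.0087),
                                intr = intrinsic_params())
  cmd <- compensate_move(m, c(100, 0))$command
  expect_equal(cmd, c(100 / 0.9913, 0), tolerance = 1e-12)
})

test_that("missing calibration fields raise a schema error naming the field", {
  expect_error(build_compensation_model(list(M_prime = 1, delta_x = 0),
                                        0, axis_errors(),
                                        intr = intrinsic_params()),
               "delta_y")
})

test_that("the model serializes and restores losslessly", {
  m <- build_compensation_model(
    list(M_prime = 0.9922, delta_x = -2.3718, delta_y = -2.7474),
    theta_deg = -5.578, axis = std_axis(),
    intr = intrinsic_params(0.993, 0.992, 600.3, 450.2, 5e-8))
  path <- withr::local_tempfile(fileext = ".json")
  write_compensation_model(m, path)
  m2 <- read_compensation_model(path)
  expect_equal(m2$M_prime, m$M_prime)
  expect_equal(m2$delta, m$delta)
  expect_equal(m2$theta_deg, m$theta_deg)
  expect_equal(unclass(m2$intr), unclass(m$intr))
  expect_equal(m2$axis[c("dxp", "dxm", "dyp", "dym")],
               m$axis[c("dxp", "dxm", "dyp", "dym")])
})

test_that("paper-literal mode evaluates the printed formula verbatim", {
  ax <- axis_errors(dxp = 0.01, dyp = 0.01)
  m <- build_compensation_model(list(M_prime = 0.99, delta_x = 2, delta_y = 3),
                                theta_deg = 10, axis = ax,
                                mode = "paper_literal",
                                intr = intrinsic_params())
  d <- c(100, 100)
  s <- sqrt(2) * 100
  mu_s <- 1.01 * sqrt(2)
  out <- compensate_move(m, d)$command
  th <- 10 * pi / 180
  expect_equal(out, c(0.99 * 2 * mu_s * s * cos(th),
                      0.99 * 3 * mu_s * s * sin(th)), tolerance = 1e-12)
})

test_that("a perfect model drives the true stage exactly (inverse consistency)", {
  truth <- std_truth()
  m <- build_compensation_model(
    list(M_prime = truth$M_true / truth$M_nominal, delta_x = 0, delta_y = 0),
    theta_deg = truth$theta_deg, axis = truth$axis, intr = truth$intr)
  set.seed(13)
  for (i in 1:25) {
    d <- runif(2, -500, 500)
    cmd <- compensate_move(m, d)$command
    ach <- forward_stage_model(truth, cmd)
    # achieved displacement, seen back in the nominal image frame
    a <- truth$theta_deg * pi / 180
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    seen <- as.numeric(rot %*% ach) * truth$M_true / truth$M_nominal
    expect_equal(seen, d, tolerance = 1e-6 / max(abs(d)))
  }
})

test_that("single-shot trials are exact under a zero-error truth", {
  truth <- std_truth(k = 0, theta_deg = 0, M_true = 20,
                     axis = axis_errors())
  m <- identity_model()
  for (s in 1:5) {
    rep <- single_shot_trial(m, truth, seed = s)
    expect_lt(rep$residual_norm, 1e-9)
    expect_equal(rep$residual_norm^2,
                 rep$residual_x^2 + rep$residual_y^2, tolerance = 1e-12)
  }
})

test_that("compensation beats the naive command under an errored truth", {
  truth <- std_truth()
  m <- build_compensation_model(
    list(M_prime = truth$M_true / truth$M_nominal, delta_x = 0, delta_y = 0),
    theta_deg = truth$theta_deg, axis = truth$axis, intr = truth$intr)
  res_c <- vapply(1:20, function(s)
    single_shot_trial(m, truth, seed = s)$residual_norm, 0)
  res_u <- vapply(1:20, function(s)
    single_shot_trial(identity_model(), truth, seed = s)$residual_norm, 0)
  expect_lt(stats::median(res_c), stats::median(res_u))
  expect_lt(max(res_c), 1e-6)
})

test_that("residuals degrade monotonically with deflection miscalibration", {
  truth <- std_truth()
  res <- vapply(c(0, 0.2, 0.5, 1, 2), function(derr) {
    m <- build_compensation_model(
      list(M_prime = truth$M_true / truth$M_nominal, delta_x = 0, delta_y = 0),
      theta_deg = truth$theta_deg + derr, axis = truth$axis,
      intr = truth$intr)
    stats::median(vapply(1:15, function(s)
      single_shot_trial(m, truth, seed = s)$residual_norm, 0))
  }, 0)
  expect_true(all(diff(res) > 0))
})

test_that("cumulative mismatch is registration-level for an error-free stage", {
  truth <- std_truth(k = 0, theta_deg = 0, M_true = 20, axis = axis_errors())
  rep <- cumulative_trial(identity_model(), truth, 1, compensated = FALSE)
  expect_lt(rep$residual_norm, 0.05)
  expect_equal(rep$meta$n_images, 5)
  rep5 <- cumulative_trial(identity_model(), truth, 5, compensated = FALSE)
  expect_equal(rep5$meta$n_images, 21)
})
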
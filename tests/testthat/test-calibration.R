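test_that("targets already satisfied return immediately as converged", {
  p <- ckd_params()
  # build targets from the model's own achieved values: zero iterations
  ach <- ckdsim:::eval_targets(p, calibration_targets(), n_eval = 400,
                               seed = 5)
  tg <- calibration_targets()
  for (i in seq_along(tg)) tg[[i]]$value <- ach[i]
  cal <- ckd_calibrate(tg, params = p, n_eval = 400, seed = 5)
  expect_true(cal$converged)
  expect_equal(cal$iterations, 0L)
  # achieved values agree up to the round-trip through the stage-gradient
  # parameterization (defaults are stored rounded)
  expect_equal(cal$achieved$achieved, ach, tolerance = 1e-4)
})

test_that("calibration recovers anchor statistics from a perturbed start", {
  # synthetic truth: anchors generated by the simulator itself under known
  # sub-model parameters; calibration from a perturbed start must reproduce
  # the anchor statistics within tolerance (the parameters themselves need
  # not be identifiable)
  truth <- ckd_params()
  small <- list(
    list(name = "gfr_slope", value = NA, tol = 0.3, cohort = "aask",
         horizon = 48, statistic = "gfr_slope"),
    list(name = "mortality", value = NA, tol = 0.4, cohort = "go",
         horizon = 36, statistic = "annual_mortality_rate")
  )
  ach <- ckdsim:::eval_targets(truth, small, n_eval = 800, seed = 9)
  for (i in seq_along(small)) small[[i]]$value <- ach[i]
  start <- truth
  start$gfr$mean <- truth$gfr$mean * 1.8
  start$mortality$level <- truth$mortality$level * 1.7
  cal <- ckd_calibrate(small, params = start, n_eval = 800, maxit = 40,
                       seed = 9)
  expect_true(all(abs(cal$achieved$achieved - cal$achieved$target) <=
                    cal$achieved$tol))
})

test_that("infeasible targets are flagged, never silently accepted", {
  tg <- list(list(name = "impossible", value = 0, tol = 0.05,
                  cohort = "go", horizon = 36,
                  statistic = "annual_mortality_rate"))
  # stage-5-heavy cohort with nonzero dialysis mortality cannot reach zero
  # annual mortality
  expect_message(
    cal <- ckd_calibrate(tg, params = ckd_params(), n_eval = 300,
                         maxit = 5, seed = 3),
    "did not reach")
  expect_false(cal$converged)
  expect_false(all(cal$achieved$within))
})

test_that("calibration targets require positive tolerances", {
  tg <- calibration_targets()
  tg[[1]]$tol <- 0
  expect_error(ckd_calibrate(tg, n_eval = 100), "tol > 0")
  expect_error(ckd_calibrate(list(), n_eval = 100), "at least one")
})

test_that("validation runs report the comparison statistics with Monte Carlo error", {
  v <- validation_run(n = 1500, seed = 11, cohort = "go", horizon = 36)
  expect_true(is.finite(v$annual_mi_rate) && v$annual_mi_rate > 0)
  expect_true(is.finite(v$annual_mortality_rate))
  expect_gt(v$annual_mi_rate_se, 0)
  # zero-hazard parameters give zero rates
  v0 <- validation_run(zero_hazard_params(), n = 300, seed = 11,
                       cohort = "go", horizon = 24)
  expect_equal(v0$annual_mi_rate, 0)
  expect_equal(v0$annual_mortality_rate, 0)
})

test_that("calibration is reproducible given seed and search config", {
  tg <- calibration_targets()[1:2]
  a <- ckd_calibrate(tg, n_eval = 300, maxit = 3, seed = 21)
  b <- ckd_calibrate(tg, n_eval = 300, maxit = 3, seed = 21)
  expect_identical(a$theta, b$theta)
  expect_identical(a$achieved, b$achieved)
})
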
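test_that("the QALY formula matches its closed forms", {
  expect_equal(qaly(rep(1, 12), rate = 0), 1)
  expect_equal(qaly(rep(0.8, 12), rate = 0), 0.8)
  expect_equal(qaly(rep(1, 24), rate = 0.03),
               sum(1.03^(-(0:23) / 12)) / 12)
  expect_equal(round(qaly(rep(1, 24), rate = 0.03), 3), 1.944)
  # discounting never increases QALYs
  u <- runif(120)
  expect_lte(qaly(u, 0.03), qaly(u, 0))
  expect_error(qaly(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("aggregates are exact functions of the per-individual indicators", {
  sim <- ckd_simulate(n = 500, seed = 13)
  s <- summary(sim)
  ind <- sim$individuals
  expect_equal(unname(s$lifetime$dialysis["risk"]), mean(ind$ever_dialysis))
  expect_equal(unname(s$lifetime$mi["risk"]), mean(ind$n_mi > 0))
  expect_equal(unname(s$qaly["mean"]), mean(ind$qaly))
  expect_equal(s$annual_mortality_rate,
               100 * sum(!ind$alive) / (sum(ind$months_at_risk) / 12))
  # discounted QALYs cannot exceed undiscounted life years
  expect_true(all(ind$qaly <= ind$months / 12 + 1e-12))
  expect_true(all(sapply(s$lifetime, function(v) v["risk"] >= 0 &
                           v["risk"] <= 1)))
})

test_that("single-individual aggregation flags the undefined dispersion", {
  sim <- ckd_simulate(n = 1, seed = 2)
  s <- summary(sim)
  expect_true(is.na(s$qaly["sd"]))
  expect_true(is.na(s$qaly["lo"]))
})

test_that("noiseless GFR trajectories give exact slopes through the aggregate", {
  p <- zero_hazard_params(gfr_mean = -0.25, gfr_sd = 0)
  coh <- make_cohort(50, age = 60, stage = 3L, gfr = 50)
  sim <- ckd_simulate(p, cohort = coh, seed = 3)
  sl <- annual_gfr_slope(sim)
  expect_equal(sl$mean, -3, tolerance = 1e-9)
  expect_equal(sl$sd, 0, tolerance = 1e-9)
  expect_equal(sl$n_excluded, 0)
})

test_that("population scaling reproduces the published arithmetic", {
  expect_equal(population_scale(0.75 - 0.52, 4e7), 9.2e6)
  expect_equal(population_scale(0.081 - 0.077, 4e7), 160000)
  expect_equal(population_scale(0, 4e7), 0)
  expect_error(population_scale(0.1, 0), "> 0")
})

test_that("common random numbers shrink the variance of arm differences", {
  n <- 600
  strat <- treatment_a(0.4)
  base <- ckd_simulate(n = n, seed = 71)
  trt_crn <- ckd_simulate(n = n, seed = 71, strategy = strat)
  trt_ind <- ckd_simulate(n = n, seed = 72, strategy = strat)
  v_crn <- var(trt_crn$individuals$qaly - base$individuals$qaly)
  v_ind <- var(trt_ind$individuals$qaly) + var(base$individuals$qaly)
  expect_lt(v_crn, v_ind)
})

test_that("one-way sweeps honour declared ranges and common random numbers", {
  # transplant utility swept over its declared range: QALYs non-decreasing
  tab <- one_way_sensitivity(c("global", "u_transplant"),
                             values = c(0.8, 0.9, 1.0), outcome = "qaly",
                             n = 800, seed = 5)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$qaly) >= 0))
  # undeclared parameter without values is an error; empty grid is an error
  expect_error(one_way_sensitivity(c("global", "u_chf"), n = 10),
               "declared range")
  expect_error(one_way_sensitivity(c("global", "p_mi_death"),
                                   values = numeric(), n = 10), "empty")
  # declared range is picked up automatically (low, default, high)
  tab2 <- one_way_sensitivity(c("global", "p_mi_death"), outcome = "cvd_death",
                              n = 400, seed = 5)
  expect_equal(tab2$value, c(0.01, 0.08, 0.15))
})

test_that("the RRR sweep table has the baseline plus one row per grid point", {
  tab <- rrr_sweep(grid = c(0.2), n = 200, seed = 7)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$arm, c("baseline", "20%"))
  expect_error(rrr_sweep(grid = numeric(), n = 10), "non-empty")
  expect_error(rrr_sweep(grid = 1.5, n = 10), "0.8")
})
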
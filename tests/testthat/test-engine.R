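test_that("with all hazards off, individuals survive to the age cap and QALYs match the discounted annuity", {
  p <- zero_hazard_params()
  coh <- make_cohort(5, age = 60, stage = 3L, gfr = 45)
  sim <- ckd_simulate(p, cohort = coh, seed = 1)
  ind <- sim$individuals
  expect_true(all(ind$months == 600L))            # (110 - 60) years
  expect_true(all(!is.na(ind$death_month)))       # cap triggers non-CVD death
  expect_true(all(ind$death_cause == "other"))
  expect_equal(ind$qaly, rep(annuity_qaly(600, 0.03) , 5), tolerance = 1e-9)
  # zero discounting: QALYs equal life years exactly
  p0 <- zero_hazard_params(discount_rate = 0)
  sim0 <- ckd_simulate(p0, cohort = coh, seed = 1)
  expect_equal(sim0$individuals$qaly, sim0$individuals$months / 12,
               tolerance = 1e-12)
})

test_that("a null month leaves state unchanged except ageing and GFR drift", {
  p <- zero_hazard_params(gfr_mean = -0.25, gfr_sd = 0)
  coh <- make_cohort(1, age = 50, stage = 3L, gfr = 45, caphos = TRUE)
  sim <- ckd_simulate(p, cohort = coh, seed = 3, horizon = 1)
  ind <- sim$individuals
  expect_true(ind$alive)
  expect_equal(ind$months, 1L)
  expect_equal(ind$n_mi + ind$n_stroke, 0L)
  expect_false(any(ind$disabled, ind$chf, ind$bone, ind$incident_htn,
                   ind$incident_diabetes, ind$incident_caphos))
})

test_that("a forced MI-death path dies of cardiovascular cause in the first month", {
  p <- zero_hazard_params()
  p$stage$mi_no_cvd <- rep(1, 5)
  p$stage$mi_with_cvd <- rep(1, 5)
  p$global$p_mi_death <- 1
  coh <- make_cohort(3, age = 60, stage = 3L, gfr = 45)
  sim <- ckd_simulate(p, cohort = coh, seed = 1)
  ind <- sim$individuals
  expect_true(all(ind$death_month == 0L))
  expect_true(all(ind$death_cause == "cvd"))
  expect_true(all(ind$n_mi == 1L))
  expect_true(all(ind$qaly == 0))                 # no accrual in death month
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- ckd_simulate(n = 300, seed = 11)
  b <- ckd_simulate(n = 300, seed = 11)
  expect_identical(a$individuals, b$individuals)
  c_ <- ckd_simulate(n = 300, seed = 12)
  expect_false(identical(a$individuals, c_$individuals))
})

test_that("death is absorbing and event logs contain nothing after death", {
  sim <- ckd_simulate(n = 150, seed = 5, log_events = TRUE)
  ev <- sim$events
  ind <- sim$individuals
  deaths <- ev[ev$event == "death", ]
  expect_equal(sort(deaths$id), sort(ind$id[!ind$alive]))
  expect_true(!anyDuplicated(deaths$id))          # at most one death each
  last <- tapply(ev$month, ev$id, max)
  dm <- ind$death_month[match(as.integer(names(last)), ind$id)]
  ok <- is.na(dm) | last <= dm
  expect_true(all(ok))
})

test_that("comorbidity flags are monotone through a lifetime", {
  # flags can only turn on: final state must include every logged onset
  sim <- ckd_simulate(n = 400, seed = 9, log_events = TRUE)
  ev <- sim$events
  ind <- sim$individuals
  for (type in c("htn", "diabetes", "caphos", "bone")) {
    ids <- unique(ev$id[ev$event == type])
    col <- switch(type, htn = "incident_htn", diabetes = "incident_diabetes",
                  caphos = "incident_caphos", bone = "bone")
    expect_true(all(ind[[col]][match(ids, ind$id)]))
  }
})

test_that("per-hazard event frequencies converge to the configured probability", {
  p <- zero_hazard_params()
  p$stage$mi_no_cvd <- rep(0.1, 5)
  p$stage$mi_with_cvd <- rep(0.1, 5)
  coh <- make_cohort(20000, age = 60, stage = 3L, gfr = 45)
  sim <- ckd_simulate(p, cohort = coh, seed = 21, horizon = 1)
  f <- mean(sim$individuals$n_mi > 0)
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(f - 0.1), 3 * se)
})

test_that("deterministic GFR drift restages on schedule and yields the exact slope", {
  p <- zero_hazard_params(gfr_mean = -0.25, gfr_sd = 0)
  coh <- make_cohort(2, age = 40, stage = 3L, gfr = 45)
  sim <- ckd_simulate(p, cohort = coh, seed = 2)
  ind <- sim$individuals
  expect_equal(ind$gfr_slope, c(-3, -3), tolerance = 1e-9)
  expect_true(all(ind$ever_dialysis | ind$ever_transplant))
  # frozen GFR: no restaging, no dialysis ever
  pc <- zero_hazard_params(gfr_mean = 0, gfr_sd = 0)
  simc <- ckd_simulate(pc, cohort = coh, seed = 2)
  expect_true(all(!simc$individuals$ever_dialysis))
  expect_equal(simc$individuals$gfr_slope, c(0, 0))
})

test_that("monthly GFR draws follow the configured normal distribution", {
  p <- zero_hazard_params(gfr_mean = -0.25, gfr_sd = 0.55)
  coh <- make_cohort(10000, age = 60, stage = 3L, gfr = 45)
  sim <- ckd_simulate(p, cohort = coh, seed = 31, horizon = 1)
  d <- sim$individuals  # one update: gfr moved by one monthly draw
  # reconstruct the draws from the slope bookkeeping is indirect; instead
  # check the mean monthly change over the cohort
  # change = slope stats not available for 1 month; use a 2-month run
  sim2 <- ckd_simulate(p, cohort = coh, seed = 31, horizon = 2)
  ch <- sim2$individuals$gfr_slope / 12    # per-month change, exact for 2 pts
  expect_equal(mean(ch), -0.25, tolerance = 0.02)
  expect_equal(sd(ch), 0.55, tolerance = 0.02)
})

test_that("renal replacement begins at the GFR trigger with the configured modality split", {
  p <- zero_hazard_params(gfr_mean = -1, gfr_sd = 0)
  coh <- make_cohort(20000, age = 50, stage = 4L, gfr = 15)
  sim <- ckd_simulate(p, cohort = coh, seed = 41, horizon = 8)
  ind <- sim$individuals
  expect_true(all(ind$ever_dialysis | ind$ever_transplant))
  f <- mean(ind$ever_transplant)
  se <- sqrt(0.023 * 0.977 / 20000)
  expect_lt(abs(f - 0.023), 3 * se)
})

test_that("dialysis mortality differs between the first year and later, and by access", {
  # catheter path: no fistula ever (placement and at-start probabilities 0)
  p <- zero_hazard_params(gfr_mean = -5, gfr_sd = 0)
  p$global$p_transplant <- 0
  p$global$p_hemodialysis <- 1
  p$global$p_dial_death_catheter_y1 <- 0.0425
  p$global$p_dial_death_catheter <- 0.0147
  n <- 40000
  coh <- make_cohort(n, age = 50, stage = 5L, gfr = 14)
  sim <- ckd_simulate(p, cohort = coh, seed = 51, horizon = 40)
  ind <- sim$individuals
  expect_true(all(ind$ever_dialysis))
  # dialysis starts at month 0; first mortality draw at month 1
  d1 <- ind$death_month[!is.na(ind$death_month) & ind$death_month == 1]
  atrisk1 <- sum(is.na(ind$death_month) | ind$death_month >= 1)
  q1 <- length(d1) / atrisk1
  expect_lt(abs(q1 - 0.0425), 3 * sqrt(0.0425 * 0.9575 / atrisk1))
  # month 14 is past the first year (12 completed months on dialysis)
  at14 <- sum(is.na(ind$death_month) | ind$death_month >= 14)
  d14 <- sum(!is.na(ind$death_month) & ind$death_month == 14)
  q14 <- d14 / at14
  expect_lt(abs(q14 - 0.0147), 3 * sqrt(0.0147 * 0.9853 / at14))
})

test_that("transplant survivors accrue the transplant utility", {
  p <- zero_hazard_params(gfr_mean = -5, gfr_sd = 0, discount_rate = 0)
  p$global$p_transplant <- 1
  p$global$p_hemodialysis <- 0
  coh <- make_cohort(1, age = 50, stage = 5L, gfr = 14)
  sim <- ckd_simulate(p, cohort = coh, seed = 6, horizon = 13)
  ind <- sim$individuals
  expect_true(ind$ever_transplant)
  # transplanted during month 0: 13 months at the transplant utility
  expect_equal(ind$qaly, 13 * 0.95 / 12, tolerance = 1e-12)
})

test_that("simulated dialysis lifetime risk matches the exact absorption probability of a miniature chain", {
  # three states: pre-dialysis CKD -> dialysis (reached at a deterministic
  # month) with a constant competing background death hazard. The chance of
  # ever reaching dialysis is (1 - q)^T * P(hemodialysis), with T background
  # draws before the transition month.
  q <- 0.02
  p <- zero_hazard_params(gfr_mean = -1, gfr_sd = 0)
  p$mortality$level <- -12 * log(1 - q)  # constant monthly death prob q
  p$mortality$shape <- 0
  p$mortality$male_hr <- 1
  # absorb quickly once on RRT (does not affect the absorption probability)
  p$global$p_dial_death_catheter_y1 <- 0.5
  p$global$p_dial_death_catheter <- 0.5
  p$global$p_dial_death_fistula <- 0.5
  p$global$p_tx_death_month <- 0.5
  n <- 50000
  coh <- make_cohort(n, age = 50, stage = 3L, gfr = 30)
  sim <- ckd_simulate(p, cohort = coh, seed = 61)
  # GFR 30 declines 1/month; first month with GFR <= 10 is month 19,
  # so 20 background draws precede RRT initiation
  exact <- (1 - q)^20 * p$global$p_hemodialysis
  f <- mean(sim$individuals$ever_dialysis)
  se <- sqrt(exact * (1 - exact) / n)
  expect_lt(abs(f - exact), 3 * se)
})

test_that("acute events apply the acute utility for one cycle only", {
  # MI certain in stage 3 only; a rising GFR restages the survivor out of
  # stage 3 after the event month, so exactly one MI fires
  p <- zero_hazard_params(gfr_mean = 5, discount_rate = 0)
  p$stage$mi_no_cvd <- c(0, 0, 1, 0, 0)
  p$stage$mi_with_cvd <- c(0, 0, 1, 0, 0)
  coh <- make_cohort(1, age = 60, stage = 3L, gfr = 59.9,
                     proteinuria = TRUE)
  sim <- ckd_simulate(p, cohort = coh, seed = 8, horizon = 3)
  # month 0: MI -> acute utility 0.1; months 1-2: utility 1
  expect_equal(sim$individuals$qaly, (0.1 + 1 + 1) / 12, tolerance = 1e-12)
  expect_equal(sim$individuals$n_mi, 1L)
})
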
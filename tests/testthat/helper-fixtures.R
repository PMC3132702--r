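# Shared fixtures: degenerate parameter sets and hand-built cohorts used to
# isolate single transitions of the monthly kernel.

# parameter set with every stochastic hazard switched off: no comorbidity
# incidence, no cardiovascular events, no background or RRT mortality, and a
# deterministic (or frozen) GFR path
zero_hazard_params <- function(gfr_mean = 0, gfr_sd = 0,
                               discount_rate = 0.03) {
  p <- ckd_params()
  p$stage[c("hypertension", "caphos", "stroke", "mi_no_cvd",
            "mi_with_cvd")] <- lapply(1:5, function(i) rep(0, 5))
  p$stage$bone_given_caphos <- rep(0, 5)
  for (nm in c("p_diabetes", "p_mi_death", "p_chf_after_mi",
               "p_stroke_disability", "p_stroke_death", "p_fistula_month",
               "p_fistula_at_start", "p_dial_death_catheter_y1",
               "p_dial_death_catheter", "p_dial_death_fistula",
               "p_tx_surgical_death", "p_tx_fail_month", "p_tx_death_month"))
    p$global[[nm]] <- 0
  p$mortality$level <- 0
  p$gfr$mean <- rep(gfr_mean, 5)
  p$gfr$sd <- rep(gfr_sd, 5)
  p$run$discount_rate <- discount_rate
  p$global$discount_rate <- discount_rate
  p
}

# a hand-built cohort of identical individuals
make_cohort <- function(n, age = 60, stage = 3L, gfr = 45,
                        male = FALSE, white = TRUE, proteinuria = FALSE,
                        diabetes = FALSE, hypertension = FALSE,
                        caphos = FALSE, cvd = FALSE) {
  data.frame(age = rep(age, n), male = rep(male, n), white = rep(white, n),
             stage = rep(as.integer(stage), n), gfr = rep(gfr, n),
             proteinuria = rep(proteinuria, n), diabetes = rep(diabetes, n),
             hypertension = rep(hypertension, n), caphos = rep(caphos, n),
             cvd = rep(cvd, n))
}

# closed-form discounted QALY total for M months at constant utility u
annuity_qaly <- function(months, rate = 0.03, u = 1) {
  sum(u * (1 + rate)^(-(seq_len(months) - 1) / 12)) / 12
}
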
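# Monthly transition kernel and lifetime simulation loop.
#
# The engine is vectorized over individuals: each simulated month one block of
# random numbers of fixed shape (N_UNIF uniforms + 1 standard normal per
# individual, dead or alive) is drawn from the seeded stream. Because the
# block shape never depends on state, two runs with the same seed consume the
# stream identically whatever the treatment arm does — this is what makes
# common-random-numbers comparisons exact and the null treatment bit-identical
# to natural history.

# uniform-draw column layout (one column per hazard class)
.U <- c(htn = 1L, diabetes = 2L, caphos = 3L, bone = 4L, mi = 5L,
        mi_death = 6L, chf = 7L, stroke = 8L, stroke_death = 9L,
        disability = 10L, bg_death = 11L, fistula = 12L, rrt_choice = 13L,
        tx_surgery = 14L, fistula_at_start = 15L, dial_death = 16L,
        tx_fail = 17L, tx_death = 18L, adherence = 19L, cvd_acq = 20L,
        bone_prog = 21L)
N_UNIF <- 21L

# strategy with no effect (natural history)
null_strategy <- function() {
  treatment_strategy(name = "natural history")
}

new_sim_state <- function(cohort, entry_month = 0L) {
  n <- nrow(cohort)
  e <- new.env(parent = emptyenv())
  e$n <- n
  e$age <- cohort$age
  e$age0 <- cohort$age
  e$male <- cohort$male
  e$white <- cohort$white
  e$stage <- as.integer(cohort$stage)
  e$gfr <- cohort$gfr
  e$proteinuria <- cohort$proteinuria
  e$diabetes <- cohort$diabetes
  e$htn <- cohort$hypertension
  e$caphos <- cohort$caphos
  e$cvd <- cohort$cvd
  e$bone <- logical(n)
  e$chf <- logical(n)
  e$disabled <- logical(n)
  e$n_mi <- integer(n)
  e$n_stroke <- integer(n)
  e$on_dialysis <- logical(n)
  e$on_transplant <- logical(n)
  e$dial_months <- integer(n)
  e$fistula <- logical(n)
  e$fistula_chance <- logical(n)
  e$ever_dialysis <- logical(n)
  e$ever_transplant <- logical(n)
  e$alive <- rep(TRUE, n)
  e$death_month <- rep(NA_integer_, n)
  e$death_cause <- rep(NA_character_, n)
  e$stage_death <- rep(NA_integer_, n)
  e$qalm <- numeric(n)
  e$months_lived <- integer(n)
  e$months_at_risk <- integer(n)
  e$incident_htn <- logical(n)
  e$incident_diabetes <- logical(n)
  e$incident_caphos <- logical(n)
  e$on_treatment <- rep(TRUE, n)
  e$acute <- logical(n)
  e$entry_month <- rep_len(as.integer(entry_month), n)
  # running sums for per-individual least-squares GFR slope (pre-RRT months)
  e$s_n <- integer(n); e$s_t <- numeric(n); e$s_tt <- numeric(n)
  e$s_g <- numeric(n); e$s_tg <- numeric(n)
  e
}

die <- function(st, idx, month, cause) {
  if (!length(idx)) return(invisible())
  st$alive[idx] <- FALSE
  st$death_month[idx] <- month
  st$death_cause[idx] <- cause
  st$stage_death[idx] <- ifelse(st$on_dialysis[idx] | st$on_transplant[idx],
                                5L, st$stage[idx])
  invisible()
}

# covariate-adjusted mean monthly GFR change for individuals idx
gfr_mean_for <- function(st, idx, gfr_model) {
  ef <- gfr_model$effects
  band <- findInterval(st$age[idx], c(40, 60, 69)) + 1L
  age_eff <- c(ef$age_20_39, ef$age_40_59, ef$age_60_69, ef$age_gt_69)[band]
  gfr_model$mean[st$stage[idx]] + age_eff +
    ef$nonwhite * !st$white[idx] +
    ef$hypertension * st$htn[idx] +
    ef$diabetes * st$diabetes[idx] +
    ef$proteinuria * st$proteinuria[idx] +
    ef$cvd * st$cvd[idx]
}

# One monthly cycle applied in place to the state environment `st`.
# `U` is an n x N_UNIF matrix of uniforms, `Z` a length-n standard normal
# vector; both cover every individual so the stream stays aligned across
# arms. Fixed within-month order: age-cap / comorbidity incidence ->
# cardiovascular events -> background non-CVD death -> GFR update,
# restaging, fistula and RRT initiation -> dialysis/transplant mortality ->
# utility accrual. Returns (invisibly) a list of event index vectors for
# optional logging.
sim_month <- function(st, m, U, Z, pp, strat) {
  sp <- pp$stage; gp <- pp$global; mort <- pp$mortality
  r <- pp$run$discount_rate
  act0 <- which(st$alive & st$entry_month <= m)
  ev <- list()
  if (!length(act0)) return(invisible(ev))

  # age cap: reaching it triggers non-CVD death
  capi <- act0[st$age[act0] >= pp$run$age_cap]
  die(st, capi, m, "other")
  act <- setdiff(act0, capi)
  if (!length(act)) {
    ev$death <- capi
    return(invisible(ev))
  }
  st$months_at_risk[act] <- st$months_at_risk[act] + 1L

  # adherence: stopping therapy is absorbing (revert to natural history)
  if (strat$stop_prob > 0) {
    stopi <- act[st$on_treatment[act] & U[act, .U["adherence"]] < strat$stop_prob]
    st$on_treatment[stopi] <- FALSE
  }
  trt <- st$on_treatment & strat$active
  cvd0 <- st$cvd            # month-start CVD status governs rows + eligibility
  rrr <- strat$rrr
  prim <- strat$primary_prevention
  ev_target <- identical(strat$target, "events")

  # (1) comorbidity incidence
  scale_for <- function(idx, key) {
    s <- rep(1, length(idx))
    if (rrr[[key]] > 0 && ev_target) s[trt[idx]] <- 1 - rrr[[key]]
    s
  }
  cand <- act[!st$htn[act]]
  newi <- cand[U[cand, .U["htn"]] <
                 sp$hypertension[st$stage[cand]] * scale_for(cand, "hypertension")]
  st$htn[newi] <- TRUE; st$incident_htn[newi] <- TRUE; ev$htn <- newi

  cand <- act[!st$diabetes[act]]
  newi <- cand[U[cand, .U["diabetes"]] <
                 gp$p_diabetes * scale_for(cand, "diabetes")]
  st$diabetes[newi] <- TRUE; st$incident_diabetes[newi] <- TRUE
  ev$diabetes <- newi

  cand <- act[!st$caphos[act]]
  newcap <- cand[U[cand, .U["caphos"]] <
                   sp$caphos[st$stage[cand]] * scale_for(cand, "caphos")]
  st$caphos[newcap] <- TRUE; st$incident_caphos[newcap] <- TRUE
  ev$caphos <- newcap
  # bone disease evaluated at incident calcium/phosphorous abnormality
  bcand <- newcap[!st$bone[newcap]]
  newb <- bcand[U[bcand, .U["bone"]] < sp$bone_given_caphos[st$stage[bcand]]]
  st$bone[newb] <- TRUE; ev$bone <- newb

  # (2) cardiovascular events
  p_mi <- ifelse(cvd0[act], sp$mi_with_cvd[st$stage[act]],
                 sp$mi_no_cvd[st$stage[act]])
  if (rrr[["mi"]] > 0 && ev_target) {
    elig <- trt[act] & (!prim | !cvd0[act])
    p_mi[elig] <- p_mi[elig] * (1 - rrr[["mi"]])
  }
  mi <- act[U[act, .U["mi"]] < p_mi]
  st$n_mi[mi] <- st$n_mi[mi] + 1L
  st$acute[mi] <- TRUE
  ev$mi <- mi
  midead <- mi[U[mi, .U["mi_death"]] < gp$p_mi_death]
  die(st, midead, m, "cvd")
  misurv <- setdiff(mi, midead)
  newchf <- misurv[!st$chf[misurv] &
                     U[misurv, .U["chf"]] < gp$p_chf_after_mi]
  st$chf[newchf] <- TRUE; ev$chf <- newchf
  acq <- misurv
  if (!ev_target && rrr[["mi"]] > 0)   # alternative mapping: prevent the
    acq <- acq[!(trt[acq] & U[acq, .U["cvd_acq"]] < rrr[["mi"]])] # CVD flag
  st$cvd[acq] <- TRUE

  a2 <- act[st$alive[act]]
  p_st <- sp$stroke[st$stage[a2]]
  if (rrr[["stroke"]] > 0 && ev_target) {
    elig <- trt[a2] & (!prim | !cvd0[a2])
    p_st[elig] <- p_st[elig] * (1 - rrr[["stroke"]])
  }
  stk <- a2[U[a2, .U["stroke"]] < p_st]
  st$n_stroke[stk] <- st$n_stroke[stk] + 1L
  st$acute[stk] <- TRUE
  ev$stroke <- stk
  stdead <- stk[U[stk, .U["stroke_death"]] < gp$p_stroke_death]
  die(st, stdead, m, "cvd")
  stsurv <- setdiff(stk, stdead)
  newdis <- stsurv[U[stsurv, .U["disability"]] < gp$p_stroke_disability]
  st$disabled[newdis] <- TRUE; ev$disabling_stroke <- newdis
  acq <- stsurv
  if (!ev_target && rrr[["stroke"]] > 0)
    acq <- acq[!(trt[acq] & U[acq, .U["cvd_acq"]] < rrr[["stroke"]])]
  st$cvd[acq] <- TRUE

  # (3) background non-CVD mortality (Gompertz in age, male hazard ratio);
  # pre-RRT individuals only — the dialysis/transplant monthly mortalities
  # already cover all-cause death on RRT
  a3 <- act[st$alive[act] & !st$on_dialysis[act] & !st$on_transplant[act]]
  h <- mort$level * exp(mort$shape * (st$age[a3] - 60)) *
    ifelse(st$male[a3], mort$male_hr, 1)
  bg <- a3[U[a3, .U["bg_death"]] < (1 - exp(-h / 12))]
  die(st, bg, m, "other")

  # (4) GFR update, restaging, fistula placement, RRT initiation
  a4 <- act[st$alive[act] & !st$on_dialysis[act] & !st$on_transplant[act]]
  if (length(a4)) {
    t_i <- m - st$entry_month[a4]          # pre-update observation at time t
    g_i <- st$gfr[a4]
    st$s_n[a4] <- st$s_n[a4] + 1L
    st$s_t[a4] <- st$s_t[a4] + t_i
    st$s_tt[a4] <- st$s_tt[a4] + t_i^2
    st$s_g[a4] <- st$s_g[a4] + g_i
    st$s_tg[a4] <- st$s_tg[a4] + t_i * g_i

    mu <- gfr_mean_for(st, a4, pp$gfr)
    if (rrr[["gfr_decline"]] > 0) {
      sl <- trt[a4] & mu < 0
      mu[sl] <- mu[sl] * (1 - rrr[["gfr_decline"]])
    }
    newgfr <- pmax(0, st$gfr[a4] + mu + pp$gfr$sd[st$stage[a4]] * Z[a4])
    old_stage <- st$stage[a4]
    new_stage <- stage_from_gfr(newgfr, marker = TRUE)
    st$gfr[a4] <- newgfr
    st$stage[a4] <- new_stage
    ev$stage_change <- a4[new_stage != old_stage]
    # bone disease re-evaluated at stage progression if still absent
    prog <- a4[new_stage > old_stage & st$caphos[a4] & !st$bone[a4]]
    newb <- prog[U[prog, .U["bone_prog"]] <
                   sp$bone_given_caphos[st$stage[prog]]]
    st$bone[newb] <- TRUE
    ev$bone <- c(ev$bone, newb)

    # fistula placement once GFR is at or below the threshold
    fcand <- a4[newgfr <= gp$fistula_gfr_threshold & !st$fistula[a4]]
    st$fistula_chance[fcand] <- TRUE
    placed <- fcand[U[fcand, .U["fistula"]] < gp$p_fistula_month]
    st$fistula[placed] <- TRUE
    ev$fistula <- placed

    # RRT initiation at GFR <= threshold
    rrt <- a4[st$gfr[a4] <= gp$rrt_gfr_threshold]
    if (length(rrt)) {
      tx <- rrt[U[rrt, .U["rrt_choice"]] < gp$p_transplant]
      txdead <- tx[U[tx, .U["tx_surgery"]] < gp$p_tx_surgical_death]
      die(st, txdead, m, "other")
      txok <- setdiff(tx, txdead)
      st$on_transplant[txok] <- TRUE
      st$ever_transplant[txok] <- TRUE
      st$ever_transplant[txdead] <- TRUE
      ev$transplant <- tx
      dial <- setdiff(rrt, tx)
      # no prior placement opportunity: default chance of a functional
      # fistula at the start of dialysis
      nofist <- dial[!st$fistula[dial] & !st$fistula_chance[dial]]
      lucky <- nofist[U[nofist, .U["fistula_at_start"]] < gp$p_fistula_at_start]
      st$fistula[lucky] <- TRUE
      st$on_dialysis[dial] <- TRUE
      st$ever_dialysis[dial] <- TRUE
      st$dial_months[dial] <- 0L
      ev$dialysis_start <- dial
    }
  }

  # (5) dialysis / transplant monthly mortality (individuals on RRT at month
  # start; same-month starters face it from the next cycle)
  tx5 <- act[st$alive[act] & st$on_transplant[act]]
  tx5 <- setdiff(tx5, if (is.null(ev$transplant)) integer() else ev$transplant)
  if (length(tx5)) {
    fail <- tx5[U[tx5, .U["tx_fail"]] < gp$p_tx_fail_month]
    st$on_transplant[fail] <- FALSE      # failed graft: revert to dialysis
    st$on_dialysis[fail] <- TRUE
    st$ever_dialysis[fail] <- TRUE
    st$dial_months[fail] <- 0L
    ev$tx_failure <- fail
    keep <- setdiff(tx5, fail)
    txd <- keep[U[keep, .U["tx_death"]] < gp$p_tx_death_month]
    die(st, txd, m, "other")
  }
  d5 <- act[st$alive[act] & st$on_dialysis[act] & st$dial_months[act] > 0L]
  if (length(d5)) {
    q <- ifelse(st$fistula[d5], gp$p_dial_death_fistula,
                ifelse(st$dial_months[d5] <= 12L,
                       gp$p_dial_death_catheter_y1, gp$p_dial_death_catheter))
    dd <- d5[U[d5, .U["dial_death"]] < q]
    die(st, dd, m, "other")
  }

  # (6) utility accrual (no accrual in the month of death)
  a6 <- act[st$alive[act]]
  if (length(a6)) {
    u <- rep(1, length(a6))
    u[st$chf[a6]] <- u[st$chf[a6]] * gp$u_chf
    u[st$disabled[a6]] <- u[st$disabled[a6]] * gp$u_disabled
    u[st$on_dialysis[a6]] <- u[st$on_dialysis[a6]] * gp$u_dialysis
    u[st$on_transplant[a6]] <- u[st$on_transplant[a6]] * gp$u_transplant
    u[st$acute[a6]] <- gp$u_acute       # acute MI/stroke overrides, one cycle
    st$qalm[a6] <- st$qalm[a6] +
      u * (1 + r)^(-(m - st$entry_month[a6]) / 12)
    st$months_lived[a6] <- st$months_lived[a6] + 1L
    # exact ageing (no accumulated floating-point drift against the age cap)
    st$age[a6] <- st$age0[a6] + st$months_lived[a6] / 12
    ondial <- a6[st$on_dialysis[a6]]
    st$dial_months[ondial] <- st$dial_months[ondial] + 1L
  }
  st$acute[act] <- FALSE
  ev$death <- act0[!st$alive[act0]]
  invisible(ev)
}

#' Run the CKD microsimulation
#'
#' Simulates each individual month by month through the natural-history
#' kernel — incident comorbidity, cardiovascular and bone events, GFR decline
#' with restaging, fistula placement, renal replacement therapy, and death —
#' accruing discounted quality-adjusted life months, until death, the age
#' cap, or an optional horizon. A treatment strategy applies relative risk
#' reductions (with adherence) to the configured hazards; a screening
#' configuration adds incident early-stage individuals each month (dynamic
#' cohort).
#'
#' Reproducibility: the run is a deterministic function of (`params`,
#' `strategy`, `cohort`/`n`, `seed`, `horizon`). Two arms run with the same
#' seed share every random draw (common random numbers); a strategy with all
#' relative risk reductions zero is bit-identical to natural history.
#'
#' @param params a `ckd_params` object (default [ckd_params()]).
#' @param n cohort size (default `params$run$n`). Ignored when `cohort` is
#'   given.
#' @param seed integer RNG seed (default `params$run$seed`).
#' @param strategy a `ckd_strategy` from [treatment_strategy()] or
#'   [treatment_a()]; `NULL` for natural history.
#' @param cohort optional baseline cohort `data.frame` (columns as produced
#'   by [sample_cohort()]); if `NULL`, `n` individuals are sampled from
#'   `params$cohort`.
#' @param horizon maximum number of months to simulate (`Inf` = lifetime);
#'   survivors at the horizon are censored.
#' @param screening optional list `list(rate =, spec =, horizon =)` enabling
#'   the dynamic cohort: `rate` new individuals per month drawn from
#'   cohort spec `spec` for `horizon` months (their discounting clock starts
#'   at entry).
#' @param log_events logical; record a per-month event log (memory-heavy,
#'   intended for small `n`).
#' @return An object of class `ckd_sim` with elements `individuals` (one row
#'   per individual: baseline characteristics, QALYs, event counts and
#'   flags, death month/cause/stage, annualized GFR slope), `events` (the
#'   log, if requested), `params`, `strategy`, `seed`, `n`, `months_run`.
#' @examples
#' sim <- ckd_simulate(n = 200, seed = 42)
#' summary(sim)
#' @export
ckd_simulate <- function(params = ckd_params(), n = params$run$n,
                         seed = params$run$seed, strategy = NULL,
                         cohort = NULL, horizon = Inf, screening = NULL,
                         log_events = FALSE) {
  validate_params(params)
  if (is.null(strategy)) strategy <- null_strategy()
  stopifnot(inherits(strategy, "ckd_strategy"))
  set.seed(as.integer(seed))

  if (is.null(cohort)) cohort <- sample_cohort(params$cohort, n)
  entry <- rep(0L, nrow(cohort))
  if (!is.null(screening)) {
    if (is.null(screening$horizon) || !is.finite(screening$horizon))
      stop("screening$horizon must be finite", call. = FALSE)
    ents <- spawn_incident_cases(screening, months = seq_len(screening$horizon))
    if (nrow(ents$cohort)) {
      cohort <- rbind(cohort, ents$cohort)
      entry <- c(entry, ents$entry_month)
    }
  }
  st <- new_sim_state(cohort, entry)
  n_tot <- st$n
  st$on_treatment <- rep(strategy$active, n_tot)

  max_months <- min(horizon,
                    ceiling((params$run$age_cap - min(st$age)) * 12) + 2)
  logs <- if (log_events) vector("list", 0L) else NULL
  m <- 0L
  while (m < max_months) {
    if (!any(st$alive)) break
    U <- matrix(stats::runif(n_tot * N_UNIF), n_tot, N_UNIF)
    Z <- stats::rnorm(n_tot)
    ev <- sim_month(st, m, U, Z, params, strategy)
    if (log_events && length(ev)) {
      rows <- lapply(names(ev), function(type) {
        ids <- ev[[type]]
        if (!length(ids)) return(NULL)
        cause <- if (type == "death") st$death_cause[ids] else NA_character_
        data.frame(month = m, id = ids, event = type, cause = cause)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) logs[[length(logs) + 1L]] <- do.call(rbind, rows)
    }
    m <- m + 1L
  }

  # per-individual least-squares GFR slope (pre-RRT), ml/min/year
  denom <- st$s_n * st$s_tt - st$s_t^2
  slope <- ifelse(st$s_n >= 2L & denom > 0,
                  12 * (st$s_n * st$s_tg - st$s_t * st$s_g) / denom, NA_real_)

  individuals <- data.frame(
    id = seq_len(n_tot),
    entry_month = st$entry_month,
    age0 = cohort$age, male = cohort$male, white = cohort$white,
    stage0 = as.integer(cohort$stage), gfr0 = cohort$gfr,
    qaly = st$qalm / 12,
    months = st$months_lived,
    months_at_risk = st$months_at_risk,
    n_mi = st$n_mi, n_stroke = st$n_stroke,
    disabled = st$disabled, chf = st$chf, bone = st$bone,
    incident_htn = st$incident_htn,
    incident_diabetes = st$incident_diabetes,
    incident_caphos = st$incident_caphos,
    ever_dialysis = st$ever_dialysis, ever_transplant = st$ever_transplant,
    alive = st$alive,
    death_month = st$death_month, death_cause = st$death_cause,
    stage_death = st$stage_death,
    gfr_slope = slope,
    gfr_obs = st$s_n
  )
  structure(list(individuals = individuals,
                 events = if (log_events) do.call(rbind, logs) else NULL,
                 params = params, strategy = strategy,
                 seed = as.integer(seed), n = n_tot, months_run = m,
                 horizon = horizon),
            class = "ckd_sim")
}

#' Simulate a single individual with a full event log
#'
#' Convenience wrapper around [ckd_simulate()] for one individual: runs the
#' monthly kernel until death or the age cap and returns the monthly event
#' log together with lifetime summaries.
#'
#' @param state one-row baseline `data.frame` in the format of
#'   [sample_cohort()].
#' @param params,strategy,seed,horizon as in [ckd_simulate()].
#' @return A list with `events` (data.frame of month/event rows) and
#'   `summary` (the one-row `individuals` table).
#' @export
run_individual <- function(state, params = ckd_params(), strategy = NULL,
                           seed = params$run$seed, horizon = Inf) {
  stopifnot(is.data.frame(state), nrow(state) == 1L)
  sim <- ckd_simulate(params, seed = seed, strategy = strategy,
                      cohort = state, horizon = horizon, log_events = TRUE)
  list(events = sim$events, summary = sim$individuals)
}

#' @export
print.ckd_sim <- function(x, ...) {
  ind <- x$individuals
  cat(sprintf("CKD microsimulation: %d individuals, %d months simulated, seed %d\n",
              x$n, x$months_run, x$seed))
  cat(sprintf("  strategy: %s\n", x$strategy$name))
  cat(sprintf("  mean QALYs %.2f | lifetime dialysis %.1f%% | lifetime MI %.1f%% | deaths %d\n",
              mean(ind$qaly), 100 * mean(ind$ever_dialysis),
              100 * mean(ind$n_mi > 0), sum(!ind$alive)))
  cat("  (use summary() for the full aggregate report)\n")
  invisible(x)
}

#' Plot a simulated cohort
#'
#' Base-graphics overview of a run: survival curve of the cohort and the
#' distribution of discounted QALYs.
#'
#' @param x a `ckd_sim` object.
#' @param ... passed to [hist()].
#' @return `x`, invisibly.
#' @export
plot.ckd_sim <- function(x, ...) {
  ind <- x$individuals
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  mo <- 0:max(ind$months)
  surv <- vapply(mo, function(m) mean(ind$months > m), numeric(1))
  plot(mo / 12, surv, type = "l", xlab = "years", ylab = "fraction alive",
       main = "Cohort survival")
  graphics::hist(ind$qaly, xlab = "discounted QALYs", main = "QALYs", ...)
  invisible(x)
}
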
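# Outcome accounting: QALYs, cohort aggregation, event rates, GFR slopes,
# paired arm comparisons and one-way sensitivity sweeps.

#' Discounted quality-adjusted life years from a utility stream
#'
#' Months lived are weighted by their health-state utility, discounted at an
#' annual rate, summed to quality-adjusted life months and divided by 12:
#' \deqn{QALY = \frac{1}{12}\sum_t u_t (1+r)^{-t/12}}
#' with `t` the 0-based month index.
#'
#' @param utilities numeric vector of monthly utilities in \[0, 1\].
#' @param rate annual discount rate.
#' @return QALYs (scalar).
#' @examples qaly(rep(1, 12), rate = 0) # one perfect year
#' @export
qaly <- function(utilities, rate = 0.03) {
  if (any(utilities < 0 | utilities > 1))
    stop("utilities must be in [0, 1]", call. = FALSE)
  if (!length(utilities)) return(0)
  t <- seq_along(utilities) - 1
  sum(utilities * monthly_discount_factor(t, rate)) / 12
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, ctr - hw), hi = min(1, ctr + hw))
}

mean_ci <- function(x, conf = 0.95) {
  n <- sum(!is.na(x))
  m <- mean(x, na.rm = TRUE)
  if (n < 2) return(c(mean = m, sd = NA_real_, lo = NA_real_, hi = NA_real_))
  s <- stats::sd(x, na.rm = TRUE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(mean = m, sd = s, lo = m - z * s / sqrt(n), hi = m + z * s / sqrt(n))
}

#' Cohort GFR slope
#'
#' Per-individual least-squares slope of pre-RRT GFR on time, annualized
#' (ml/min/year), averaged over the cohort. Individuals with fewer than two
#' pre-RRT GFR observations are excluded and counted.
#'
#' @param sim a `ckd_sim` object.
#' @return List with `mean`, `sd`, `n`, `n_excluded`.
#' @export
annual_gfr_slope <- function(sim) {
  sl <- sim$individuals$gfr_slope
  ok <- !is.na(sl)
  list(mean = mean(sl[ok]), sd = stats::sd(sl[ok]), n = sum(ok),
       n_excluded = sum(!ok))
}

#' Aggregate a simulated cohort
#'
#' Computes the cohort-level output quantities: mean discounted QALYs (with
#' SD and normal-approximation 95% CI), undiscounted life years, lifetime
#' risks of each tracked event as the mean of per-individual indicators
#' (with Wilson 95% CIs), annualized MI and all-cause mortality rates
#' (events per person-year at risk), the mean annualized pre-RRT GFR slope,
#' and the mean CKD stage at death (dialysis/transplant encoded as stage 5,
#' configurable via `rrt_stage`).
#'
#' @param object a `ckd_sim` object.
#' @param rrt_stage stage value assigned at death to individuals on renal
#'   replacement therapy (default 5).
#' @param ... unused.
#' @return An object of class `summary.ckd_sim` (a list of named
#'   statistics), printable as a table.
#' @export
summary.ckd_sim <- function(object, rrt_stage = 5L, ...) {
  ind <- object$individuals
  n <- nrow(ind)
  py <- sum(ind$months_at_risk) / 12
  risks <- list(
    dialysis = ind$ever_dialysis,
    transplant = ind$ever_transplant,
    mi = ind$n_mi > 0,
    stroke = ind$n_stroke > 0,
    disabled = ind$disabled,
    chf = ind$chf,
    bone_disease = ind$bone,
    incident_diabetes = ind$incident_diabetes,
    incident_hypertension = ind$incident_htn,
    cvd_death = !is.na(ind$death_cause) & ind$death_cause == "cvd"
  )
  lifetime <- lapply(risks, function(x) {
    k <- sum(x)
    c(risk = k / n, wilson_ci(k, n))
  })
  dead <- !ind$alive
  sdth <- ind$stage_death[dead]
  if (!identical(rrt_stage, 5L)) {
    rrt <- (ind$ever_dialysis | ind$ever_transplant)[dead]
    sdth[rrt] <- rrt_stage
  }
  sl <- annual_gfr_slope(object)
  structure(list(
    n = n, deaths = sum(dead), person_years = py,
    qaly = mean_ci(ind$qaly),
    life_years = mean_ci(ind$months / 12),
    lifetime = lifetime,
    annual_mi_rate = 100 * sum(ind$n_mi) / py,
    annual_stroke_rate = 100 * sum(ind$n_stroke) / py,
    annual_mortality_rate = 100 * sum(dead) / py,
    gfr_slope = sl,
    mean_stage_at_death = if (any(dead)) mean(sdth) else NA_real_,
    seed = object$seed, strategy = object$strategy$name
  ), class = "summary.ckd_sim")
}

#' @export
print.summary.ckd_sim <- function(x, ...) {
  cat(sprintf("Cohort aggregate report — %s (n = %d, seed = %d)\n",
              x$strategy, x$n, x$seed))
  q <- x$qaly
  cat(sprintf("  QALYs (discounted):   %6.2f  SD %.2f  [%.2f, %.2f]\n",
              q["mean"], q["sd"], q["lo"], q["hi"]))
  cat(sprintf("  Life years:           %6.2f\n", x$life_years["mean"]))
  cat("  Lifetime risks (%, Wilson 95% CI):\n")
  for (nm in c("dialysis", "mi", "stroke", "disabled", "cvd_death")) {
    v <- x$lifetime[[nm]]
    cat(sprintf("    %-22s %6.2f  [%.2f, %.2f]\n", nm,
                100 * v["risk"], 100 * v["lo"], 100 * v["hi"]))
  }
  cat(sprintf("  Annual MI rate:       %6.2f %%/yr\n", x$annual_mi_rate))
  cat(sprintf("  Annual mortality:     %6.2f %%/yr\n",
              x$annual_mortality_rate))
  cat(sprintf("  GFR slope:            %6.2f (SD %.2f) ml/min/yr (n = %d, %d excluded)\n",
              x$gfr_slope$mean, x$gfr_slope$sd, x$gfr_slope$n,
              x$gfr_slope$n_excluded))
  cat(sprintf("  Mean CKD stage at death: %.2f\n", x$mean_stage_at_death))
  invisible(x)
}

#' Scale a per-person risk difference to a population count
#'
#' Multiplies a per-person lifetime-risk difference by a population size,
#' e.g. to express how many events a treatment would add or avert in the
#' whole US CKD population.
#'
#' @param delta per-person difference (e.g. difference of lifetime risks).
#' @param population population size (> 0).
#' @param digits optional number of significant digits to round to.
#' @return Population count.
#' @examples population_scale(0.75 - 0.52, 4e7)
#' @export
population_scale <- function(delta, population, digits = NULL) {
  if (population <= 0) stop("population must be > 0", call. = FALSE)
  x <- delta * population
  if (!is.null(digits)) x <- signif(x, digits)
  x
}

#' Compare a treatment strategy against natural history
#'
#' Runs the natural-history arm and the treatment arm under common random
#' numbers (same seed, hence the same baseline cohort and the same
#' random-draw stream) and reports the per-person differences in the main
#' outputs with paired 95% confidence intervals.
#'
#' @param strategy a `ckd_strategy`.
#' @param params,n,seed,horizon as in [ckd_simulate()].
#' @return An object of class `ckd_comparison`: list with both `ckd_sim`
#'   runs and a `delta` table.
#' @export
compare_arms <- function(strategy, params = ckd_params(),
                         n = params$run$n, seed = params$run$seed,
                         horizon = Inf) {
  base <- ckd_simulate(params, n = n, seed = seed, horizon = horizon)
  trt <- ckd_simulate(params, n = n, seed = seed, strategy = strategy,
                      horizon = horizon)
  b <- base$individuals; t_ <- trt$individuals
  paired <- function(db) {
    m <- mean_ci(db)
    data.frame(delta = m["mean"], lo = m["lo"], hi = m["hi"])
  }
  out <- rbind(
    qaly = paired(t_$qaly - b$qaly),
    dialysis = paired(as.numeric(t_$ever_dialysis) -
                        as.numeric(b$ever_dialysis)),
    mi = paired(as.numeric(t_$n_mi > 0) - as.numeric(b$n_mi > 0)),
    stroke = paired(as.numeric(t_$n_stroke > 0) -
                      as.numeric(b$n_stroke > 0)),
    disabled = paired(as.numeric(t_$disabled) - as.numeric(b$disabled)),
    cvd_death = paired(as.numeric(!is.na(t_$death_cause) &
                                    t_$death_cause == "cvd") -
                         as.numeric(!is.na(b$death_cause) &
                                      b$death_cause == "cvd"))
  )
  structure(list(baseline = base, treatment = trt, delta = out,
                 strategy = strategy),
            class = "ckd_comparison")
}

#' @export
print.ckd_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison (common random numbers): %s vs natural history\n",
              x$strategy$name))
  cat("Per-person differences (treatment - natural history), 95% CI:\n")
  print(round(x$delta, 5))
  invisible(x)
}

#' Sweep the primary-prevention relative risk reduction
#'
#' Runs the natural-history baseline and [treatment_a()] at each requested
#' relative risk reduction under common random numbers, and tabulates QALYs
#' and the lifetime risks of dialysis, MI, stroke, disabling stroke and
#' cardiovascular death — the standard output table of the primary-prevention
#' experiment.
#'
#' @param grid numeric vector of RRR values in \[0, 0.8\] (baseline row is
#'   always included).
#' @param params,n,seed as in [ckd_simulate()].
#' @return A data.frame with one row per arm.
#' @export
rrr_sweep <- function(grid = c(0.2, 0.4, 0.6, 0.8), params = ckd_params(),
                      n = params$run$n, seed = params$run$seed) {
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  if (any(grid < 0 | grid > 0.8))
    stop("grid values must be in [0, 0.8]", call. = FALSE)
  arms <- c(list(NULL), lapply(grid, treatment_a))
  labs <- c("baseline", sprintf("%.0f%%", 100 * grid))
  rows <- lapply(seq_along(arms), function(i) {
    sim <- ckd_simulate(params, n = n, seed = seed, strategy = arms[[i]])
    s <- summary(sim)
    data.frame(
      rrr = c(0, grid)[i], arm = labs[i],
      qalys = unname(s$qaly["mean"]),
      dialysis = 100 * unname(s$lifetime$dialysis["risk"]),
      mi = 100 * unname(s$lifetime$mi["risk"]),
      stroke = 100 * unname(s$lifetime$stroke["risk"]),
      disabled = 100 * unname(s$lifetime$disabled["risk"]),
      cvd_mortality = 100 * unname(s$lifetime$cvd_death["risk"])
    )
  })
  do.call(rbind, rows)
}

#' One-way sensitivity analysis
#'
#' Re-evaluates an outcome over a grid of values of a single parameter,
#' holding everything else (including the random-number seed: common random
#' numbers) fixed. Parameters are addressed by path into the `ckd_params`
#' object, e.g. `c("global", "p_mi_death")`. If `values` is omitted the
#' parameter must have a declared plausible range in
#' `params$global$ranges`, and (low, default, high) is used.
#'
#' @param param character path to the parameter.
#' @param values numeric grid; optional when a declared range exists.
#' @param outcome one of `"qaly"`, `"dialysis"`, `"mi"`, `"stroke"`,
#'   `"cvd_death"`, `"mean_stage_at_death"`.
#' @param params,n,seed,strategy as in [ckd_simulate()].
#' @return Data.frame with columns `value` and `outcome`.
#' @export
one_way_sensitivity <- function(param, values = NULL, outcome = "qaly",
                                params = ckd_params(), n = 2000,
                                seed = params$run$seed, strategy = NULL) {
  get_path <- function(p, path) Reduce(`[[`, path, p)
  set_path <- function(p, path, v) {
    if (length(path) == 1L) { p[[path]] <- v; return(p) }
    p[[path[1L]]] <- set_path(p[[path[1L]]], path[-1L], v)
    p
  }
  if (is.null(values)) {
    rg <- params$global$ranges[[param[length(param)]]]
    if (is.null(rg))
      stop(sprintf("parameter '%s' has no declared range; supply `values`",
                   paste(param, collapse = "$")), call. = FALSE)
    values <- sort(unique(c(rg[1], get_path(params, param), rg[2])))
  }
  if (!length(values)) stop("empty value grid", call. = FALSE)
  extract <- function(s) switch(outcome,
    qaly = unname(s$qaly["mean"]),
    dialysis = 100 * unname(s$lifetime$dialysis["risk"]),
    mi = 100 * unname(s$lifetime$mi["risk"]),
    stroke = 100 * unname(s$lifetime$stroke["risk"]),
    cvd_death = 100 * unname(s$lifetime$cvd_death["risk"]),
    mean_stage_at_death = s$mean_stage_at_death,
    stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE))
  res <- vapply(values, function(v) {
    p2 <- set_path(params, param, v)
    # transplant utility keeps its constructed relation when swept directly
    sim <- ckd_simulate(p2, n = n, seed = seed, strategy = strategy)
    extract(summary(sim))
  }, numeric(1))
  out <- data.frame(value = values, outcome = res)
  names(out)[2] <- outcome
  out
}
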
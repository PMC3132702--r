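#' Model parameters for the CKD microsimulation
#'
#' Assemble the full parameter set of the simulation: stage-dependent monthly
#' event probabilities, stage-independent probabilities and utilities, the
#' monthly GFR-change model, the background (non-cardiovascular) mortality
#' model, the baseline cohort specification, and run settings. With no
#' arguments the published default tables are returned; any component can be
#' replaced wholesale or modified via `...` using `path$to$field` semantics
#' handled by [modifyList()].
#'
#' All probabilities are monthly probabilities stored as proportions in
#' \[0, 1\]; utilities are preference weights in \[0, 1\] (0 = dead,
#' 1 = perfect health); GFR is in ml/min and GFR change in ml/min per month.
#'
#' @param stage list of per-stage (1-5) monthly probabilities: incident
#'   hypertension, incident calcium/phosphorous abnormality, bone disease
#'   conditional on calcium/phosphorous abnormality, stroke, MI without
#'   pre-existing cardiovascular disease, MI with pre-existing CVD.
#' @param global list of stage-independent probabilities, utilities,
#'   thresholds and the annual discount rate (see [default_global_params()]).
#' @param gfr monthly GFR-change model: per-stage mean and standard deviation
#'   plus additive covariate effects on the mean (see [default_gfr_model()]).
#' @param mortality background non-CVD mortality model (Gompertz in age with
#'   a male hazard ratio), see [default_mortality_model()].
#' @param cohort baseline cohort specification, see [default_cohort_spec()].
#' @param run run settings: `n`, `seed`, `discount_rate`, `age_cap`.
#' @param validate logical; run [validate_params()] on the result.
#'
#' @return An object of class `ckd_params`: a named list with components
#'   `stage`, `global`, `gfr`, `mortality`, `cohort`, `run`.
#' @seealso [read_ckd_config()], [write_ckd_config()], [ckd_simulate()]
#' @examples
#' p <- ckd_params()
#' p$global$u_dialysis
#' p$stage$mi_no_cvd[5]
#' @export
ckd_params <- function(stage = default_stage_params(),
                       global = default_global_params(),
                       gfr = default_gfr_model(),
                       mortality = default_mortality_model(),
                       cohort = default_cohort_spec(),
                       run = default_run_config(),
                       validate = TRUE) {
  p <- structure(list(stage = stage, global = global, gfr = gfr,
                      mortality = mortality, cohort = cohort, run = run),
                 class = "ckd_params")
  if (validate) validate_params(p)
  p
}

#' @export
print.ckd_params <- function(x, ...) {
  cat("CKD microsimulation parameter set\n")
  cat(sprintf("  stages 1-5 monthly MI (no CVD): %s\n",
              paste(format(x$stage$mi_no_cvd), collapse = " ")))
  cat(sprintf("  dialysis utility %.2f, transplant utility %.2f, discount %.1f%%/yr\n",
              x$global$u_dialysis, x$global$u_transplant,
              100 * x$global$discount_rate))
  cat(sprintf("  GFR change mean (ml/min/mo) by stage: %s\n",
              paste(format(x$gfr$mean), collapse = " ")))
  cat(sprintf("  background mortality: level %.4g /yr at 60, shape %.3f /yr, male HR %.2f\n",
              x$mortality$level, x$mortality$shape, x$mortality$male_hr))
  cat(sprintf("  default run: n = %d, seed = %d, age cap %g\n",
              x$run$n, x$run$seed, x$run$age_cap))
  invisible(x)
}

#' Default stage-dependent monthly event probabilities
#'
#' Monthly probabilities of CKD-related complications by CKD stage (1-5):
#' incident hypertension, incident calcium/phosphorous abnormality, bone
#' disease conditional on a calcium/phosphorous abnormality, stroke, and
#' myocardial infarction with and without pre-existing cardiovascular
#' disease.
#'
#' @return Named list of numeric vectors of length 5 (stages 1-5).
#' @export
default_stage_params <- function() {
  list(
    hypertension     = c(0.0008, 0.004, 0.006, 0.006, 0.006),
    caphos           = c(0.00001, 0.00005, 0.0001, 0.0001, 0.0003),
    bone_given_caphos = c(0, 0.80, 0.90, 1.00, 1.00),
    stroke           = c(0.00003, 0.00003, 0.00003, 0.00006, 0.00006),
    mi_no_cvd        = c(0.0005, 0.0007, 0.0013, 0.0013, 0.0048),
    mi_with_cvd      = c(0.0027, 0.0031, 0.0050, 0.0050, 0.0100)
  )
}

#' Default stage-independent probabilities, utilities and thresholds
#'
#' Utilities: acute MI/stroke month 0.1, CHF 0.76, death 0, disabled from
#' stroke 0.35, dialysis 0.8, transplant 0.95 (three-fourths of the distance
#' from the dialysis utility to perfect health, see [transplant_utility()]).
#' Event probabilities: monthly diabetes incidence 0.005% (5e-5), death from
#' acute MI 8% (plausible range 1-15%), CHF after acute MI 5% (1-15%),
#' moderate-severe disability after stroke 33%, death from acute stroke 20%.
#' Renal replacement therapy: hemodialysis chosen with probability 0.977 and
#' transplant 0.023 at a GFR of 10 ml/min or less; fistula placement is
#' attempted at 25%/month once GFR is at or below 30 ml/min, and individuals
#' reaching dialysis with no prior opportunity for placement have a functional
#' fistula with probability 0.25. Monthly dialysis mortality: catheter first
#' year 4.25%, catheter thereafter 1.47%, fistula 1.33%. Transplant: surgical
#' mortality 1.2%, monthly failure 0.51% (failure reverts to dialysis
#' permanently), monthly mortality 0.31%. Discounting: 3% per year.
#'
#' `ranges` holds (low, high) bounds for the parameters the sensitivity
#' module may sweep.
#'
#' @return Named list.
#' @export
default_global_params <- function() {
  list(
    u_acute            = 0.1,
    u_chf              = 0.76,
    u_death            = 0,
    u_disabled         = 0.35,
    u_dialysis         = 0.8,
    u_transplant       = 0.95,
    p_diabetes         = 0.00005,
    p_mi_death         = 0.08,
    p_chf_after_mi     = 0.05,
    p_stroke_disability = 0.33,
    p_stroke_death     = 0.20,
    p_hemodialysis     = 0.977,
    p_transplant       = 0.023,
    fistula_gfr_threshold = 30,
    p_fistula_month    = 0.25,
    p_fistula_at_start = 0.25,
    p_dial_death_catheter_y1 = 0.0425,
    p_dial_death_catheter    = 0.0147,
    p_dial_death_fistula     = 0.0133,
    p_tx_surgical_death = 0.012,
    p_tx_fail_month    = 0.0051,
    p_tx_death_month   = 0.0031,
    rrt_gfr_threshold  = 10,
    discount_rate      = 0.03,
    ranges = list(
      p_mi_death     = c(0.01, 0.15),
      p_chf_after_mi = c(0.01, 0.15),
      u_transplant   = c(0.8, 1.0)
    )
  )
}

#' Default monthly GFR-change model
#'
#' The monthly change in GFR is drawn from a normal distribution whose mean is
#' a per-stage baseline plus additive covariate effects (age band, non-white
#' race, hypertension, diabetes, proteinuria, pre-existing CVD) and whose
#' standard deviation is per-stage. The distribution permits both improvement
#' and decline. The per-stage baselines and standard deviations shipped here
#' are calibrated values: they were fitted with [ckd_calibrate()] against the
#' published validation anchors (cohort GFR slope, annual MI and mortality
#' rates, and the baseline QALY / lifetime dialysis figures), because the
#' underlying regression is not published. Covariate effects default to zero
#' (the anchors cannot identify them); users with their own longitudinal data
#' may supply values in ml/min/month.
#'
#' @return Named list with `mean` (length 5), `sd` (length 5), `effects`
#'   (named additive effects on the mean, ml/min/month).
#' @export
default_gfr_model <- function() {
  list(
    # calibrated: decline magnitude log-linear in stage, shared monthly SD
    mean = c(-0.0075457, -0.0148986, -0.0294166, -0.0580816, -0.114679),
    sd   = rep(0.488351, 5),
    effects = list(
      age_20_39 = 0, age_40_59 = 0, age_60_69 = 0, age_gt_69 = 0,
      nonwhite = 0, hypertension = 0, diabetes = 0,
      proteinuria = 0, cvd = 0
    )
  )
}

#' Default background (non-cardiovascular) mortality model
#'
#' Mortality from causes other than acute cardiovascular events, dialysis and
#' transplantation is modelled as a Gompertz hazard in age:
#' \deqn{h(a) = \lambda \exp\{\beta (a - 60)\} \cdot HR_{male}^{[male]}}
#' with `level` \eqn{\lambda} the annual hazard at age 60 for women, `shape`
#' \eqn{\beta} the log-hazard slope per year of age, and `male_hr` a fixed
#' male:female hazard ratio. The monthly death probability is
#' `1 - exp(-h/12)`. Level and shape are calibrated to the published
#' validation anchors with [ckd_calibrate()] (they are not published);
#' the male hazard ratio of 1.5 is a documented assumption and is
#' config-overridable.
#'
#' @return Named list with `level`, `shape`, `male_hr`.
#' @export
default_mortality_model <- function() {
  list(level = 0.0061423, shape = 0.0498061, male_hr = 1.5) # calibrated
}

#' Default run settings
#' @return Named list with `n` (10000 individuals), `seed`, `discount_rate`
#'   (0.03/yr), `age_cap` (110 years; reaching it triggers non-CVD death).
#' @export
default_run_config <- function() {
  list(n = 10000L, seed = 1L, discount_rate = 0.03, age_cap = 110)
}

#' Validate a parameter set
#'
#' Checks every probability and utility is in \[0, 1\], the death utility is
#' exactly 0, MI probability with pre-existing CVD is at least the
#' probability without (per stage), the hemodialysis and transplant choice
#' probabilities sum to 1, GFR-change standard deviations are positive, and
#' the cohort specification is internally consistent (distributions sum to 1
#' after normalization, proportions in \[0, 1\]).
#'
#' @param p a `ckd_params` object.
#' @return `p`, invisibly; otherwise stops with an error naming the offending
#'   field.
#' @export
validate_params <- function(p) {
  chk01 <- function(x, name) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
      stop(sprintf("parameter '%s' must be in [0, 1]", name), call. = FALSE)
  }
  sp <- p$stage
  need <- c("hypertension", "caphos", "bone_given_caphos", "stroke",
            "mi_no_cvd", "mi_with_cvd")
  for (nm in need) {
    if (is.null(sp[[nm]]) || length(sp[[nm]]) != 5L)
      stop(sprintf("stage parameter '%s' missing or not length 5", nm),
           call. = FALSE)
    chk01(sp[[nm]], paste0("stage$", nm))
  }
  if (any(sp$mi_with_cvd < sp$mi_no_cvd))
    stop("stage$mi_with_cvd must be >= stage$mi_no_cvd for every stage",
         call. = FALSE)

  gp <- p$global
  probs <- c("p_diabetes", "p_mi_death", "p_chf_after_mi",
             "p_stroke_disability", "p_stroke_death", "p_hemodialysis",
             "p_transplant", "p_fistula_month", "p_fistula_at_start",
             "p_dial_death_catheter_y1", "p_dial_death_catheter",
             "p_dial_death_fistula", "p_tx_surgical_death", "p_tx_fail_month",
             "p_tx_death_month")
  utils_ <- c("u_acute", "u_chf", "u_death", "u_disabled", "u_dialysis",
              "u_transplant")
  for (nm in c(probs, utils_)) {
    if (is.null(gp[[nm]]))
      stop(sprintf("global parameter '%s' missing", nm), call. = FALSE)
    chk01(gp[[nm]], paste0("global$", nm))
  }
  if (gp$u_death != 0)
    stop("global$u_death must be exactly 0", call. = FALSE)
  if (abs(gp$p_hemodialysis + gp$p_transplant - 1) > 1e-9)
    stop("global$p_hemodialysis + global$p_transplant must sum to 1",
         call. = FALSE)
  if (gp$discount_rate < 0)
    stop("global$discount_rate must be >= 0", call. = FALSE)

  g <- p$gfr
  if (length(g$mean) != 5L || length(g$sd) != 5L)
    stop("gfr$mean and gfr$sd must have length 5", call. = FALSE)
  if (any(g$sd < 0)) stop("gfr$sd must be >= 0", call. = FALSE)

  m <- p$mortality
  if (m$level < 0 || m$male_hr <= 0)
    stop("mortality$level must be >= 0 and mortality$male_hr > 0",
         call. = FALSE)

  validate_cohort_spec(p$cohort)

  r <- p$run
  if (r$n < 1) stop("run$n must be >= 1", call. = FALSE)
  if (r$discount_rate < 0) stop("run$discount_rate must be >= 0",
                                call. = FALSE)
  invisible(p)
}

#' Convert a monthly probability to an annual probability
#'
#' `1 - (1 - p)^12`: the probability of at least one event in 12 independent
#' monthly cycles. Used to compare monthly transition probabilities against
#' annualized cohort-study rates.
#'
#' @param p monthly probability in \[0, 1\] (vectorized).
#' @return Annual probability.
#' @examples annualize(0.0048)
#' @export
annualize <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  1 - (1 - p)^12
}

#' Monthly discount factor
#'
#' Present-value weight `(1 + rate)^(-month/12)` applied to utilities accrued
#' in month `month` (0-based) under an annual discount rate. No half-cycle
#' correction is applied.
#'
#' @param month month index, 0-based (vectorized).
#' @param rate annual discount rate (default 0.03).
#' @return Discount factor in (0, 1\].
#' @examples monthly_discount_factor(12, 0.03) # one year out
#' @export
monthly_discount_factor <- function(month, rate = 0.03) {
  if (any(month < 0)) stop("month must be >= 0", call. = FALSE)
  (1 + rate)^(-month / 12)
}

#' Transplant utility from the dialysis utility
#'
#' The utility of life with a functioning kidney transplant, constructed as
#' the value three-fourths of the distance on the utility scale from the
#' dialysis utility to perfect health: `d + 0.75 * (perfect - d)`. With the
#' default dialysis utility of 0.8 this gives 0.95.
#'
#' @param dialysis utility of dialysis.
#' @param perfect utility of perfect health (default 1).
#' @return Utility.
#' @examples transplant_utility(0.8)
#' @export
transplant_utility <- function(dialysis, perfect = 1) {
  if (any(dialysis < 0) || any(perfect > 1) || any(dialysis > perfect))
    stop("require 0 <= dialysis <= perfect <= 1", call. = FALSE)
  dialysis + 0.75 * (perfect - dialysis)
}

# ---- config I/O -------------------------------------------------------------

#' Read a simulation configuration
#'
#' Load a full parameter set from a YAML configuration document (sections
#' `stage`, `global`, `gfr`, `mortality`, `cohort`, `run`, mirroring
#' [ckd_params()]), or return the built-in defaults with
#' `read_ckd_config("defaults")`. Unknown keys are errors (fail-fast);
#' missing required fields and out-of-range probabilities raise validation
#' errors naming the field.
#'
#' @param source path to a YAML file, or the string `"defaults"`.
#' @return A validated `ckd_params` object.
#' @seealso [write_ckd_config()]; the shipped default document is at
#'   `system.file("extdata", "default-config.yaml", package = "ckdsim")`.
#' @export
read_ckd_config <- function(source = "defaults") {
  if (identical(source, "defaults")) return(ckd_params())
  if (!file.exists(source))
    stop(sprintf("config file '%s' not found", source), call. = FALSE)
  raw <- yaml::yaml.load_file(source)
  base <- ckd_params(validate = FALSE)
  known <- names(base)
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop(sprintf("unknown config section(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  for (sec in names(raw)) {
    extra <- setdiff(names(raw[[sec]]), names(base[[sec]]))
    if (length(extra))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(extra, collapse = ", ")), call. = FALSE)
    base[[sec]] <- utils::modifyList(base[[sec]], raw[[sec]])
  }
  # vectors of length 5 may arrive as lists from YAML
  base$stage <- lapply(base$stage, function(x) as.numeric(unlist(x)))
  base$gfr$mean <- as.numeric(unlist(base$gfr$mean))
  base$gfr$sd <- as.numeric(unlist(base$gfr$sd))
  base$cohort <- normalize_cohort_spec_types(base$cohort)
  validate_params(base)
  base
}

#' Write a simulation configuration
#'
#' Serialize a `ckd_params` object to a YAML document readable by
#' [read_ckd_config()]. Round-tripping the default parameter set is
#' bit-exact.
#'
#' @param p a `ckd_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ckd_config <- function(p, path) {
  stopifnot(inherits(p, "ckd_params"))
  x <- unclass(p)
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}
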
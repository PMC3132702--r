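# Treatment strategies: relative risk reductions with adherence, plus the
# dynamic-cohort (screening) entry process.

.rrr_outcomes <- c("mi", "stroke", "hypertension", "diabetes", "caphos",
                   "gfr_decline")

#' Define a treatment strategy
#'
#' A strategy maps outcome hazards to relative risk reductions (RRR) in
#' \[0, 1\], applied multiplicatively as `p * (1 - rrr)` while the individual
#' remains on treatment. Adherence is a monthly probability of stopping
#' therapy; stopping is absorbing — the individual reverts to natural history
#' permanently.
#'
#' Seven named intervention templates are recognized (ACEI/ARB, statin,
#' nephrology care, diabetes control, blood-pressure control,
#' calcium/phosphorous management, screening). Their effect sizes are not
#' published, so the templates ship with empty (zero) RRRs: users must supply
#' effect sizes for any real analysis. The hypothetical primary-prevention
#' strategy with a known structure is [treatment_a()].
#'
#' @param name strategy label.
#' @param rrr named numeric vector of relative risk reductions; recognized
#'   names: `mi`, `stroke`, `hypertension`, `diabetes`, `caphos`,
#'   `gfr_decline`. Unnamed outcomes default to 0.
#' @param primary_prevention logical; if `TRUE`, the `mi` and `stroke`
#'   reductions apply only to individuals without pre-existing cardiovascular
#'   disease (first-event prevention).
#' @param target `"events"` (default: RRRs scale the event hazards) or
#'   `"cvd_acquisition"` (alternative mapping: RRRs scale the probability
#'   that an event survivor acquires the chronic CVD flag).
#' @param stop_prob monthly probability of stopping therapy, in \[0, 1\].
#' @param dynamic logical; marks the strategy as a screening/dynamic-cohort
#'   strategy.
#' @return An object of class `ckd_strategy`.
#' @export
treatment_strategy <- function(name = "custom", rrr = numeric(),
                               primary_prevention = FALSE,
                               target = c("events", "cvd_acquisition"),
                               stop_prob = 0, dynamic = FALSE) {
  target <- match.arg(target)
  full <- stats::setNames(numeric(length(.rrr_outcomes)), .rrr_outcomes)
  if (length(rrr)) {
    bad <- setdiff(names(rrr), .rrr_outcomes)
    if (length(bad))
      stop(sprintf("unknown outcome hazard(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    if (any(rrr < 0 | rrr > 1))
      stop("relative risk reductions must be in [0, 1]", call. = FALSE)
    full[names(rrr)] <- rrr
  }
  if (stop_prob < 0 || stop_prob > 1)
    stop("stop_prob must be in [0, 1]", call. = FALSE)
  structure(list(name = name, rrr = full,
                 primary_prevention = primary_prevention,
                 target = target, stop_prob = stop_prob,
                 dynamic = dynamic,
                 active = any(full > 0) || stop_prob > 0),
            class = "ckd_strategy")
}

#' @export
print.ckd_strategy <- function(x, ...) {
  cat(sprintf("CKD treatment strategy '%s'%s\n", x$name,
              if (!x$active) " (no effect: natural history)" else ""))
  nz <- x$rrr[x$rrr > 0]
  if (length(nz))
    cat(sprintf("  RRR: %s%s (target: %s)\n",
                paste(sprintf("%s %.0f%%", names(nz), 100 * nz),
                      collapse = ", "),
                if (x$primary_prevention) " [primary prevention only]" else "",
                x$target))
  if (x$stop_prob > 0)
    cat(sprintf("  monthly stop probability %.1f%%\n", 100 * x$stop_prob))
  invisible(x)
}

#' Named intervention templates
#'
#' Returns one of the seven named strategy templates with user-supplied
#' effect sizes (all default to zero because no effect sizes are published
#' for them).
#'
#' @param which one of `"acei_arb"`, `"statin"`, `"nephrology_care"`,
#'   `"diabetes_control"`, `"bp_control"`, `"caphos_management"`,
#'   `"screening"`.
#' @param rrr,stop_prob passed to [treatment_strategy()].
#' @return A `ckd_strategy`.
#' @export
strategy_template <- function(which = c("acei_arb", "statin",
                                        "nephrology_care", "diabetes_control",
                                        "bp_control", "caphos_management",
                                        "screening"),
                              rrr = numeric(), stop_prob = 0) {
  which <- match.arg(which)
  treatment_strategy(name = which, rrr = rrr, stop_prob = stop_prob,
                     dynamic = identical(which, "screening"))
}

#' Apply a relative risk reduction to a probability
#'
#' `p * (1 - rrr)`.
#'
#' @param p probability in \[0, 1\] (vectorized).
#' @param rrr relative risk reduction in \[0, 1\].
#' @return Adjusted probability.
#' @examples apply_rrr(0.0048, 0.2)
#' @export
apply_rrr <- function(p, rrr) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (any(rrr < 0 | rrr > 1)) stop("rrr must be in [0, 1]", call. = FALSE)
  p * (1 - rrr)
}

#' The hypothetical primary-prevention strategy (TREATMENT A)
#'
#' A treatment that reduces the development of new (pre-clinical) vascular
#' disease by a relative risk reduction `rrr_vasc`. The model carries no
#' explicit asymptomatic vascular-disease state, so by default the effect is
#' mapped to the primary-prevention event hazards: the first-MI and
#' first-stroke hazards of individuals without pre-existing cardiovascular
#' disease are scaled by `1 - rrr_vasc`. An alternative mapping
#' (`target = "cvd_acquisition"`) scales the probability that an event
#' survivor acquires the chronic CVD flag instead. Adherence is complete
#' (stop probability 0) and there are no adverse treatment events.
#'
#' @param rrr_vasc relative risk reduction in \[0, 0.8\].
#' @param target see [treatment_strategy()].
#' @return A `ckd_strategy`.
#' @examples treatment_a(0.2)
#' @export
treatment_a <- function(rrr_vasc, target = "events") {
  if (rrr_vasc < 0 || rrr_vasc > 0.8)
    stop("rrr_vasc must be in [0, 0.8]", call. = FALSE)
  treatment_strategy(name = sprintf("TREATMENT A (RRRvasc = %.0f%%)",
                                    100 * rrr_vasc),
                     rrr = c(mi = rrr_vasc, stroke = rrr_vasc),
                     primary_prevention = TRUE, target = target,
                     stop_prob = 0)
}

#' One adherence step
#'
#' Monthly adherence update: an individual on treatment stops with
#' probability `stop_prob`; once off treatment the state is absorbing
#' (permanent reversion to natural history).
#'
#' @param on_treatment logical vector.
#' @param stop_prob monthly stop probability in \[0, 1\].
#' @return Updated logical vector.
#' @export
adherence_step <- function(on_treatment, stop_prob) {
  if (stop_prob < 0 || stop_prob > 1)
    stop("stop_prob must be in [0, 1]", call. = FALSE)
  on_treatment & (stats::runif(length(on_treatment)) >= stop_prob)
}

#' Screening configuration for a dynamic cohort
#'
#' In dynamic (screening) mode newly identified early-stage CKD individuals
#' enter the cohort each month. Entry volumes depend on the screened
#' population and are not published; they must be user-supplied.
#'
#' @param rate integer number of entrants per month (>= 0).
#' @param spec entry-cohort specification (a `ckd_cohort_spec`); default
#'   restricts the standard cohort to stages 1-2.
#' @param horizon simulation horizon in months (finite).
#' @return A list of class `ckd_screening`.
#' @export
screening_config <- function(rate, spec = early_stage_spec(),
                             horizon = 240) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (!is.finite(horizon)) stop("horizon must be finite", call. = FALSE)
  structure(list(rate = as.integer(rate), spec = spec,
                 horizon = as.integer(horizon)),
            class = "ckd_screening")
}

#' @rdname screening_config
#' @export
early_stage_spec <- function() {
  cs <- default_cohort_spec()
  cs$stage_dist <- cs$stage_dist * c(1, 1, 0, 0, 0)
  cs$stage_dist <- cs$stage_dist / sum(cs$stage_dist)
  cs
}

#' Sample incident cases for a dynamic cohort
#'
#' Draws the entrants for the given months from the entry-cohort
#' specification; each entrant is tagged with an entry month, and their
#' utility-discounting clock starts at entry.
#'
#' @param screening a `ckd_screening` from [screening_config()].
#' @param months integer vector of entry months (1-based).
#' @return A list with `cohort` (data.frame of entrants) and `entry_month`.
#' @export
spawn_incident_cases <- function(screening, months) {
  stopifnot(inherits(screening, "ckd_screening"))
  k <- screening$rate * length(months)
  if (k == 0L)
    return(list(cohort = sample_cohort(screening$spec, 1)[0, ],
                entry_month = integer()))
  list(cohort = sample_cohort(screening$spec, k),
       entry_month = rep(as.integer(months), each = screening$rate))
}
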
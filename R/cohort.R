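#' Default baseline cohort specification
#'
#' Per-stage marginal distributions of baseline characteristics for the US
#' CKD population: proportion male, proportion white, age-band distribution
#' (20-39, 40-59, 60-69, >69 years), and prevalence of proteinuria, diabetes,
#' hypertension, calcium/phosphorous abnormalities and pre-existing
#' cardiovascular disease, plus the CKD stage distribution itself.
#'
#' Two published irregularities are handled minimally: the printed stage
#' distribution and some age-band columns do not sum exactly to 1 and are
#' renormalized at validation; the first printed age band is read as 20-39 so
#' the bands tile the axis; the stage-5 proteinuria prevalence is not
#' published (carried forward from stage 4).
#'
#' GFR at baseline is drawn uniformly within each stage's band: stage 1
#' \[90, 110\], stage 2 \[60, 90), stage 3 \[30, 60), stage 4 \[15, 30),
#' stage 5 \[10, 15) — stage 5 starts at 10 ml/min so no one begins below the
#' renal-replacement trigger.
#'
#' @return A list of class `ckd_cohort_spec`.
#' @export
default_cohort_spec <- function() {
  structure(list(
    stage_dist  = c(0.303, 0.272, 0.390, 0.026, 0.015),
    male        = c(0.658, 0.565, 0.378, 0.359, 0.359),
    white       = c(0.395, 0.480, 0.475, 0.435, 0.200),
    age_bands = list(
      s1 = c(0.551, 0.251, 0.101, 0.097),
      s2 = c(0.160, 0.340, 0.230, 0.270),
      s3 = c(0.019, 0.048, 0.232, 0.697),
      s4 = c(0.015, 0.015, 0.302, 0.668),
      s5 = c(0.000, 0.050, 0.100, 0.850)
    ),
    proteinuria = c(0.143, 0.143, 0.061, 0.426, 0.426),
    diabetes    = c(0.189, 0.221, 0.169, 0.171, 0.171),
    hypertension = c(0.241, 0.353, 0.465, 0.516, 0.940),
    caphos      = c(0.030, 0.150, 0.500, 0.700, 0.850),
    cvd         = c(0.100, 0.129, 0.176, 0.250, 0.600),
    gfr_bands = list(
      s1 = c(90, 110), s2 = c(60, 90), s3 = c(30, 60),
      s4 = c(15, 30), s5 = c(10, 15)
    ),
    age_band_edges = c(20, 40, 60, 69, 90)
  ), class = "ckd_cohort_spec")
}

# coerce YAML-loaded lists back to the numeric shapes the sampler expects
normalize_cohort_spec_types <- function(cs) {
  num <- c("stage_dist", "male", "white", "proteinuria", "diabetes",
           "hypertension", "caphos", "cvd", "age_band_edges")
  for (nm in num) cs[[nm]] <- as.numeric(unlist(cs[[nm]]))
  cs$age_bands <- lapply(cs$age_bands, function(x) as.numeric(unlist(x)))
  cs$gfr_bands <- lapply(cs$gfr_bands, function(x) as.numeric(unlist(x)))
  class(cs) <- "ckd_cohort_spec"
  cs
}

#' Validate a cohort specification
#'
#' All proportions must lie in \[0, 1\]; the stage distribution and every
#' age-band distribution must sum to 1 within 1e-9 after renormalization
#' (negative weights are errors).
#'
#' @param cs a `ckd_cohort_spec`.
#' @return `cs` invisibly, or an error naming the field.
#' @export
validate_cohort_spec <- function(cs) {
  prop <- c("stage_dist", "male", "white", "proteinuria", "diabetes",
            "hypertension", "caphos", "cvd")
  for (nm in prop) {
    x <- cs[[nm]]
    if (is.null(x) || length(x) != 5L || anyNA(x) || any(x < 0 | x > 1))
      stop(sprintf("cohort$%s must be 5 proportions in [0, 1]", nm),
           call. = FALSE)
  }
  if (sum(cs$stage_dist) <= 0)
    stop("cohort$stage_dist must have positive mass", call. = FALSE)
  for (i in 1:5) {
    b <- cs$age_bands[[i]]
    if (length(b) != 4L || anyNA(b) || any(b < 0))
      stop(sprintf("cohort$age_bands[[%d]] must be 4 non-negative weights", i),
           call. = FALSE)
    if (sum(b) <= 0)
      stop(sprintf("cohort$age_bands[[%d]] has no mass", i), call. = FALSE)
  }
  invisible(cs)
}

#' CKD stage from GFR
#'
#' National Kidney Foundation staging: stage 1 is GFR >= 90 and stage 2 is
#' GFR 60-89, both requiring a urinary marker (proteinuria or hematuria);
#' stage 3 is GFR 30-59, stage 4 is 15-29, stage 5 is below 15. A GFR of 60
#' or more without a marker is not CKD ("at risk", coded 0).
#'
#' @param gfr GFR in ml/min (vectorized, must be >= 0).
#' @param marker logical; proteinuria or hematuria present.
#' @return Integer stage 1-5, or 0 for at-risk.
#' @examples stage_from_gfr(45, FALSE); stage_from_gfr(95, TRUE)
#' @export
stage_from_gfr <- function(gfr, marker = TRUE) {
  if (any(gfr < 0)) stop("gfr must be >= 0", call. = FALSE)
  marker <- rep_len(as.logical(marker), length(gfr))
  s <- integer(length(gfr))
  s[gfr < 60] <- 3L
  s[gfr < 30] <- 4L
  s[gfr < 15] <- 5L
  s[gfr >= 60 & marker] <- 2L
  s[gfr >= 90 & marker] <- 1L
  s
}

#' Sample ages from an age-band distribution
#'
#' Draws a band from the (renormalized) band weights, then an age uniformly
#' within the band. Bands are 20-39, 40-59, 60-69 and >69; the open top band
#' is drawn uniformly on (69, 90\].
#'
#' @param bands numeric vector of 4 non-negative band weights.
#' @param n number of draws.
#' @param edges band edges (default `c(20, 40, 60, 69, 90)`).
#' @return Numeric vector of ages in years.
#' @export
sample_age <- function(bands, n, edges = c(20, 40, 60, 69, 90)) {
  if (length(bands) != 4L || anyNA(bands) || any(bands < 0) || sum(bands) <= 0)
    stop("bands must be 4 non-negative weights with positive mass",
         call. = FALSE)
  b <- sample.int(4L, n, replace = TRUE, prob = bands / sum(bands))
  stats::runif(n, min = edges[b], max = edges[b + 1L])
}

#' Sample a baseline cohort
#'
#' Each individual is drawn by (1) CKD stage from the stage distribution,
#' then (2) each attribute independently from that stage's marginals (the
#' published tables give marginals only; no joint structure is invented).
#' GFR is uniform within the stage's band; age is drawn with [sample_age()].
#'
#' @param spec a `ckd_cohort_spec` (default [default_cohort_spec()]).
#' @param n number of individuals.
#' @return A `data.frame` with one row per individual: `age`, `male`,
#'   `white`, `stage`, `gfr`, `proteinuria`, `diabetes`, `hypertension`,
#'   `caphos`, `cvd`. Draw it inside a [set.seed()] context (or via
#'   [ckd_simulate()]) for reproducibility.
#' @examples
#' set.seed(1)
#' head(sample_cohort(n = 5))
#' @export
sample_cohort <- function(spec = default_cohort_spec(), n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  validate_cohort_spec(spec)
  sd_ <- spec$stage_dist / sum(spec$stage_dist)
  stage <- sample.int(5L, n, replace = TRUE, prob = sd_)
  age <- numeric(n)
  for (s in 1:5) {
    idx <- which(stage == s)
    if (length(idx))
      age[idx] <- sample_age(spec$age_bands[[s]], length(idx),
                             edges = spec$age_band_edges)
  }
  lo <- vapply(spec$gfr_bands, `[`, numeric(1), 1L)
  hi <- vapply(spec$gfr_bands, `[`, numeric(1), 2L)
  gfr <- stats::runif(n, lo[stage], hi[stage])
  draw <- function(p) stats::runif(n) < p[stage]
  data.frame(
    age = age,
    male = draw(spec$male),
    white = draw(spec$white),
    stage = stage,
    gfr = gfr,
    proteinuria = draw(spec$proteinuria),
    diabetes = draw(spec$diabetes),
    hypertension = draw(spec$hypertension),
    caphos = draw(spec$caphos),
    cvd = draw(spec$cvd)
  )
}
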
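---
title: "The ckdsim microsimulation model: structure, parameters, calibration"
author: "ckdsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ckdsim microsimulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ckdsim` is a patient-level (Monte Carlo) state-transition model of chronic
kidney disease with a fixed cycle length of one month. One individual at a
time is walked from a sampled baseline state to death (or an optional
horizon), so transition probabilities may depend on the individual's full
history — prior events, acquired comorbidity, time on dialysis — which a
cohort-level Markov model cannot represent.

Health states comprise CKD stages 1–5 (NKF staging by GFR band, with stages
1–2 requiring a urinary marker), hemodialysis with catheter or fistula
access, functioning kidney transplant, and death; superimposed condition
flags track hypertension, diabetes, calcium/phosphorous abnormality, bone
disease, congestive heart failure, stroke-related disability and
pre-existing cardiovascular disease. Condition flags are monotone: once
acquired they persist for life. Peritoneal dialysis and costs are out of
scope.

Severity is driven by a continuous GFR (ml/min). Each pre-RRT month the GFR
changes by a draw from a normal distribution whose mean is a per-stage
baseline plus additive covariate effects (age band, non-white race,
hypertension, diabetes, proteinuria, CVD — all zero by default, see
*Calibration*) and whose SD is per-stage; the distribution permits both
improvement and decline, so individuals can improve a stage through the
positive tail. GFR is floored at 0. When GFR falls to 10 ml/min or below,
renal replacement therapy begins: transplant with probability 0.023
(surgical mortality 1.2%), otherwise hemodialysis; a failed transplant
(0.51%/month) reverts to dialysis permanently. Fistula placement is
attempted at 25%/month once GFR ≤ 30 ml/min; an individual reaching
dialysis with no prior months below that threshold has a functional fistula
with probability 0.25. Placement is treated as immediately functional (no
maturation lag is specified anywhere we could anchor one); this is
config-overridable by setting the placement probability to zero and relying
on the at-start probability.

### Within-month ordering

The published description does not fix an ordering of competing events
within a cycle, so the kernel applies a fixed, auditable order; competing
draws within a month are independent:

1. age-cap check (reaching 110 years triggers non-CVD death);
2. comorbidity incidence — hypertension (per stage), diabetes (global
   5e-5/month, stored literally as printed), calcium/phosphorous
   abnormality (per stage) with a conditional bone-disease evaluation;
3. cardiovascular events — MI using the with/without-CVD row matching the
   month-start CVD status, then acute-MI death (8%) and CHF-after-MI (5%)
   sub-draws; stroke, then acute-stroke death (20%) and disability (33%)
   sub-draws; survivors acquire the CVD flag;
4. background non-CVD mortality (pre-RRT individuals only; Gompertz in
   age with a male hazard ratio of 1.5 — see *Calibration*);
5. GFR update, restaging, fistula placement, RRT initiation;
6. dialysis/transplant monthly mortality (all-cause for those states;
   individuals starting RRT this month face it from the next cycle);
7. utility accrual.

Bone disease is evaluated once in the month a calcium/phosphorous
abnormality first appears and re-evaluated at each subsequent stage
progression while still absent, using the per-stage conditional
probabilities (the 100% entries make a per-month interpretation
degenerate). Individuals whose abnormality is prevalent at baseline are
evaluated at their next stage progression, not at entry — baseline bone
disease prevalence is not part of the cohort tables, and evaluating
prevalent abnormality at month 0 would immediately hand most of the cohort
bone disease.

### Utilities and QALY accounting

Utilities: dialysis 0.8, transplant 0.95 (constructed as three-fourths of
the distance from dialysis to perfect health), CHF 0.76, disabled-by-stroke
0.35, death 0; an acute MI or stroke sets the month's utility to 0.1 for
that single cycle, overriding everything else. CKD stages per se carry
utility 1.0 (no stage utilities are published), as does bone disease (no
utility is published for it). Concurrent chronic states combine
multiplicatively (e.g. CHF on dialysis: 0.76 × 0.8); this and the acute
override are config-overridable conventions. A non-disabling stroke leaves
no chronic decrement (none is published).

Each lived month contributes `u · (1+r)^(−t/12)` quality-adjusted
life-months, with `t` counted from the individual's entry (so dynamic-mode
entrants discount from their entry month) and `r` = 0.03/yr by default;
QALYs are the sum divided by 12. No half-cycle correction is applied. The
death month accrues no utility but counts as exposure for event rates;
annual rates are events per person-year at risk.

## Random numbers, reproducibility, paired arms

Every month the engine draws a fixed-shape block of random numbers — one
uniform per hazard class per individual (dead or alive) plus one standard
normal for the GFR innovation — from a single stream seeded by the run
seed. Because the block's shape never depends on simulation state, two runs
with the same seed consume the stream identically whatever the treatment
arm does. Consequences, all tested: identical seed and configuration give
bit-identical results; a treatment arm and the natural-history arm run with
the same seed are exact common-random-numbers pairs; a strategy with all
relative risk reductions zero is bit-identical to natural history; and
per-individual paired deltas have strictly smaller variance than
independent-arm deltas. Drawing for dead individuals costs a constant
factor but keeps the alignment exact.

## Treatment strategies

A strategy maps outcome hazards to relative risk reductions applied as
`p · (1 − RRR)` while on treatment; a monthly stop probability moves
individuals back to natural history permanently. Seven named intervention
templates ship with empty (zero) effect sizes because no effect sizes are
published for them; they are configuration slots, not evidence.

The hypothetical primary-prevention treatment (`treatment_a(rrr_vasc)`)
reduces the development of new vascular disease. The model has no explicit
asymptomatic vascular-disease state, so the default mapping applies
`rrr_vasc` to the first-MI and first-stroke hazards of individuals without
pre-existing CVD; an alternative mapping
(`target = "cvd_acquisition"`) scales the probability that an event
survivor acquires the chronic CVD flag instead. The default is the
interpretation with observable consequences at every RRR level. One
structural consequence is worth stating plainly: under a proportional
reduction of a first-event hazard with competing mortality, the relative
reduction in cumulative lifetime incidence can never exceed the hazard
reduction itself (and falls short of it when the event is common, because
averted early events extend exposure). Published sweep patterns steeper
than that are unattainable under this mapping, whatever the calibration;
the acceptance suite reports such discrepancies rather than hiding them.

## Calibration of the unpublished sub-models

Two sub-models that the published tables do not contain are required to
close the model: the per-stage GFR-change distribution and background
non-CVD mortality (without which all-cause mortality cannot reach its
validation value). Both are fitted by `ckd_calibrate()` — Nelder–Mead over
a five-parameter vector: GFR decline log-linear in stage (two parameters),
a shared monthly GFR SD, and the Gompertz level and shape — minimizing the
sum of squared standardized distances to the anchors:

* annual MI rate 3.6 %/yr and annual all-cause mortality 1.6 %/yr on the
  managed-care-emulating validation cohort over 36 months;
* mean annualized pre-RRT GFR slope −3.0 ml/min/yr on the trial-emulating
  validation cohort over 48 months;
* soft checks: baseline mean QALYs 17.6 and lifetime dialysis risk 7.7% on
  the default cohort (tolerances chosen by this package).

Covariate effects on GFR default to zero: five anchors cannot identify
nine covariate coefficients, so calibration touches stage-level structure
only. Every objective evaluation runs the simulator at reduced size
(n = 2000–3000) under a fixed seed, making the objective deterministic and
the search reproducible; the shipped defaults are the result of this fit,
and re-running `ckd_calibrate()` on them verifies the anchors and returns
after the initial evaluation (zero iterations) when they still hold.
Non-convergence is flagged with the achieved values, never silently
accepted. The parameters themselves are not claimed identifiable — the
anchor-statistic match is the contract, which is what the
parameter-recovery test checks.

The two validation cohort specifications are *approximate emulations*
assembled a priori from the studies' designs (stage mix, age mix, race,
comorbidity prevalence, follow-up length); they are editable data, not
facts, and are documented in `go_cohort_spec()` / `aask_cohort_spec()`.

## The synthetic cohort generator

`sample_cohort()` draws stage from the published stage distribution, then
each attribute independently from that stage's marginals, age uniformly
within its band and GFR uniformly within the stage's band (stage 5 starts
at [10, 15) so nobody begins below the RRT trigger). It emulates the
marginal structure of the US CKD population; it does **not** emulate
within-stage correlations between attributes (only marginals are
published, and any joint structure would be invented), secular trends, or
measurement error in staging. Passing tests therefore demonstrate correct
behaviour under independent marginals, not under realistic attribute
correlation. Printed irregularities are repaired minimally: the first age
band is read as 20–39 so bands tile, non-unit column sums are
renormalized, and the unpublished stage-5 proteinuria prevalence carries
the stage-4 value.

## Numerical and degenerate-input choices

GFR is floored at 0; stage-5 GFR below the trigger initiates RRT in the
same month's step 5. Zero GFR SD is allowed (used by tests to force
deterministic trajectories). A cohort of one is allowed; dispersion is
reported as `NA` and flagged. Per-individual GFR slopes use the
closed-form least-squares estimate accumulated online over pre-RRT months;
individuals with fewer than two observations are excluded and counted.
Probabilities are validated into [0, 1] at load time with the offending
field named; unknown configuration keys are errors. The discounting clock
is 0-based (`monthly_discount_factor(0) = 1`).

## Problem sizes

The defaults follow the published experiment: 10,000 individuals per arm
for headline runs, 100,000 draws for distributional checks of the sampler,
50,000 for the absorption-probability oracle, and n = 2000–3000 per
calibration evaluation. The test suite uses smaller cohorts (200–1000)
wherever only a direction or an exact identity is being checked.

## Known limitations

* No costs, no peritoneal dialysis, no within-month event multiplicity
  (at most one MI draw per month).
* MI and stroke hazards depend on stage and CVD status only (no direct age
  dependence); background mortality carries all age dependence.
* The male:female background hazard ratio (1.5) is an assumption, not a
  published value.
* Attribute independence within stage (above).
* Validation-cohort emulations are approximate by construction.
* Several published headline figures are not mutually derivable from the
  published monthly inputs under any parameterization of the unpublished
  sub-models; where that happens the acceptance suite shows the model's
  actual value rather than an adjusted one.

## A worked micro-example

```{r, eval = FALSE}
library(ckdsim)
sim <- ckd_simulate(n = 2000, seed = 1)
summary(sim)

cmp <- compare_arms(treatment_a(0.2), n = 2000, seed = 1)
cmp$delta
```
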
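# ckdsim — patient-level microsimulation of chronic kidney disease

`ckdsim` is an R implementation of a general-purpose decision model of
chronic kidney disease (CKD) for clinical and policy analysis. It answers
questions of the form *"what happens to quality-adjusted survival, dialysis
incidence, myocardial infarction and stroke burden if a CKD population
receives intervention X?"* — accounting for the competing risks that make
such questions hard: preventing cardiac deaths keeps people alive long
enough for their kidneys to fail.

## The model

The core is a discrete-time individual-level (Markov Monte Carlo)
simulation with a one-month cycle. Each simulated person carries a
continuous GFR (ml/min), a CKD stage (NKF staging: stage 3 = GFR 30–59,
stage 4 = 15–29, stage 5 = < 15; stages 1–2 require a urinary marker), and
monotone condition flags (hypertension, diabetes, calcium/phosphorous
abnormality, bone disease, CHF, stroke disability, cardiovascular disease).
Each month, in a fixed order: incident comorbidity; MI and stroke (with
acute case-fatality, CHF and disability sub-draws); background non-CVD
death (Gompertz in age); a GFR innovation `ΔGFR ~ N(μ_stage + covariates,
σ_stage)` with restaging; fistula placement (25 %/month below GFR 30);
renal replacement at GFR ≤ 10 (transplant with p = 0.023, else
hemodialysis); modality-specific RRT mortality; and utility accrual.

The primary outcome is discounted quality-adjusted life years,

QALY = (1/12) Σₜ uₜ (1 + r)^(−t/12),  r = 0.03/yr,

with utilities 0.8 (dialysis), 0.95 (transplant), 0.76 (CHF), 0.35
(disabled by stroke), 0.1 for the month of an acute MI/stroke, 0 (dead).
Treatments act as relative risk reductions `p(1 − RRR)` with an absorbing
monthly stop probability; arms run under common random numbers, so a null
treatment is bit-identical to natural history. Two sub-models that the
published tables do not contain — the per-stage GFR-change distribution and
background mortality — are calibrated (Nelder–Mead on simulated anchors) to
published validation values; see the methods vignette
(`vignettes/ckd-microsimulation.Rmd`).

## Worked example

```r
library(ckdsim)

# natural history of the default US CKD cohort (10,000 individuals)
sim <- ckd_simulate(n = 10000, seed = 1)
summary(sim)

# hypothetical primary prevention of vascular disease, 20% risk reduction,
# paired with natural history by common random numbers
cmp <- compare_arms(treatment_a(0.2), n = 10000, seed = 1)
cmp$delta
```

`summary(sim)` prints (numbers from the run above):

```
Cohort aggregate report — natural history (n = 10000, seed = 1)
  QALYs (discounted):    17.99  SD 8.13  [17.83, 18.15]
  Life years:            31.48
  Lifetime risks (%, Wilson 95% CI):
    dialysis                 6.83  [6.35, 7.34]
    mi                      34.28  [33.36, 35.22]
    stroke                   1.20  [1.00, 1.43]
    disabled                 0.36  [0.26, 0.50]
    cvd_death                5.46  [5.03, 5.92]
  Annual MI rate:         2.07 %/yr
  Annual mortality:       3.17 %/yr
  GFR slope:             -0.30 (SD 0.67) ml/min/yr (n = 9977, 23 excluded)
  Mean CKD stage at death: 2.54
```

and `cmp$delta` gives the paired treatment effects:

```
             delta       lo       hi
qaly       0.07044  0.05176  0.08913
dialysis   0.00030 -0.00004  0.00064
mi        -0.03790 -0.04165 -0.03415
stroke    -0.00180 -0.00272 -0.00088
disabled  -0.00050 -0.00094 -0.00006
cvd_death -0.00600 -0.00751 -0.00449
```

Read it as: mean discounted quality-adjusted survival of the cohort; the
fraction ever starting dialysis or ever having an MI over their remaining
lifetime (with Wilson 95% intervals); lifetime-average annualized event
rates; the mean per-individual pre-dialysis GFR slope; and the mean CKD
stage at which individuals die (dialysis/transplant counted as stage 5).
The paired comparison table gives per-person treatment effects with 95%
CIs — QALYs gained, MI risk averted, and the accompanying *increase* in
lifetime dialysis risk, the model's characteristic competing-risk effect.

The command-line interface wraps the same functions:

```sh
inst/cli/ckdsim run --n 10000 --seed 1 --out results/
inst/cli/ckdsim table4 --grid 0.2,0.4,0.6,0.8 --n 10000 --seed 1
```

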
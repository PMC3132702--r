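# Default configuration of the CKD microsimulation.
# Sections mirror ckd_params(): stage-dependent monthly event
# probabilities (proportions), stage-independent probabilities/utilities,
# the monthly GFR-change model (ml/min/month; stage means and SDs are
# calibrated values, covariate effects default to zero), background
# non-CVD Gompertz mortality (level = annual hazard at age 60, female),
# the baseline cohort marginals by CKD stage, and run settings.
# Unknown keys are rejected at load time.
stage:
  hypertension:
  - 0.0008
  - 0.004
  - 0.006
  - 0.006
  - 0.006
  caphos:
  - 1.0e-05
  - 5.0e-05
  - 1.0e-04
  - 1.0e-04
  - 3.0e-04
  bone_given_caphos:
  - 0.0
  - 0.8
  - 0.9
  - 1.0
  - 1.0
  stroke:
  - 3.0e-05
  - 3.0e-05
  - 3.0e-05
  - 6.0e-05
  - 6.0e-05
  mi_no_cvd:
  - 0.0005
  - 0.0007
  - 0.0013
  - 0.0013
  - 0.0048
  mi_with_cvd:
  - 0.0027
  - 0.0031
  - 0.005
  - 0.005
  - 0.01
global:
  u_acute: 0.1
  u_chf: 0.76
  u_death: 0.0
  u_disabled: 0.35
  u_dialysis: 0.8
  u_transplant: 0.95
  p_diabetes: 5.0e-05
  p_mi_death: 0.08
  p_chf_after_mi: 0.05
  p_stroke_disability: 0.33
  p_stroke_death: 0.2
  p_hemodialysis: 0.977
  p_transplant: 0.023
  fistula_gfr_threshold: 30.0
  p_fistula_month: 0.25
  p_fistula_at_start: 0.25
  p_dial_death_catheter_y1: 0.0425
  p_dial_death_catheter: 0.0147
  p_dial_death_fistula: 0.0133
  p_tx_surgical_death: 0.012
  p_tx_fail_month: 0.0051
  p_tx_death_month: 0.0031
  rrt_gfr_threshold: 10.0
  discount_rate: 0.03
  ranges:
    p_mi_death:
    - 0.01
    - 0.15
    p_chf_after_mi:
    - 0.01
    - 0.15
    u_transplant:
    - 0.8
    - 1.0
gfr:
  mean:
  - -0.0075457
  - -0.0148986
  - -0.0294166
  - -0.0580816
  - -0.114679
  sd:
  - 0.488351
  - 0.488351
  - 0.488351
  - 0.488351
  - 0.488351
  effects:
    age_20_39: 0.0
    age_40_59: 0.0
    age_60_69: 0.0
    age_gt_69: 0.0
    nonwhite: 0.0
    hypertension: 0.0
    diabetes: 0.0
    proteinuria: 0.0
    cvd: 0.0
mortality:
  level: 0.0061423
  shape: 0.0498061
  male_hr: 1.5
cohort:
  stage_dist:
  - 0.303
  - 0.272
  - 0.39
  - 0.026
  - 0.015
  male:
  - 0.658
  - 0.565
  - 0.378
  - 0.359
  - 0.359
  white:
  - 0.395
  - 0.48
  - 0.475
  - 0.435
  - 0.2
  age_bands:
    s1:
    - 0.551
    - 0.251
    - 0.101
    - 0.097
    s2:
    - 0.16
    - 0.34
    - 0.23
    - 0.27
    s3:
    - 0.019
    - 0.048
    - 0.232
    - 0.697
    s4:
    - 0.015
    - 0.015
    - 0.302
    - 0.668
    s5:
    - 0.0
    - 0.05
    - 0.1
    - 0.85
  proteinuria:
  - 0.143
  - 0.143
  - 0.061
  - 0.426
  - 0.426
  diabetes:
  - 0.189
  - 0.221
  - 0.169
  - 0.171
  - 0.171
  hypertension:
  - 0.241
  - 0.353
  - 0.465
  - 0.516
  - 0.94
  caphos:
  - 0.03
  - 0.15
  - 0.5
  - 0.7
  - 0.85
  cvd:
  - 0.1
  - 0.129
  - 0.176
  - 0.25
  - 0.6
  gfr_bands:
    s1:
    - 90.0
    - 110.0
    s2:
    - 60.0
    - 90.0
    s3:
    - 30.0
    - 60.0
    s4:
    - 15.0
    - 30.0
    s5:
    - 10.0
    - 15.0
  age_band_edges:
  - 20.0
  - 40.0
  - 60.0
  - 69.0
  - 90.0
run:
  'n': 10000
  seed: 1
  discount_rate: 0.03
  age_cap: 110.0

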
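Package: ckdsim
Title: Patient-Level Microsimulation of Chronic Kidney Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-time (monthly cycle) individual-level Markov Monte
    Carlo model of chronic kidney disease natural history: GFR decline and
    restaging, incident comorbidity (hypertension, diabetes,
    calcium/phosphorous abnormality, bone disease), cardiovascular events
    (myocardial infarction, stroke, congestive heart failure), renal
    replacement therapy (hemodialysis with catheter or fistula access,
    transplantation), and death. Produces discounted quality-adjusted life
    years, lifetime event risks, annualized event rates and GFR slopes with
    Monte Carlo uncertainty; supports relative-risk-reduction treatment
    strategies with adherence, dynamic (screening) cohorts, one-way
    sensitivity sweeps, and calibration of the unpublished GFR-change and
    background-mortality sub-models to published validation anchors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
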
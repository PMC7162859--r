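Package: neuropk
Title: Translational Pharmacokinetics and Pharmacodynamics of CNS Drug Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis chain for preclinical brain drug-delivery studies:
    non-compartmental analysis (AUC, terminal slope, half-life, clearance,
    volume of distribution) of plasma and brain concentration-time profiles,
    unbound-fraction estimation from rapid equilibrium dialysis with
    homogenate-dilution correction, total and unbound partition coefficients
    (Kp, Kp,uu) and distribution advantage, regional tumor partitioning,
    Hill-equation dose-response fitting, unbound-exposure scenario analysis
    (fold-change scaling and time above a potency threshold), exponential
    tumor-growth kinetics from bioluminescence, and Kaplan-Meier / log-rank
    survival analysis. Includes seed-reproducible simulators for every input
    so the full pipeline is testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
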
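Package: ipscpop
Title: Population Simulations of Human iPSC-Derived Cardiomyocyte
    Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the electrophysiology of human induced pluripotent stem
    cell-derived cardiomyocytes (hiPSC-CMs) with a Hodgkin-Huxley-type ordinary
    differential equation model of the ventricular-like phenotype (two
    compartments, 13 membrane currents, sarcoplasmic-reticulum calcium
    handling), including temperature and extracellular-concentration
    adaptation via Q10 rescaling of gating kinetics. Extracts action-potential
    and calcium-transient biomarkers from simulated or externally recorded
    traces, builds experimentally calibrated populations of models by Latin
    hypercube sampling of 22 conductance and kinetics parameters against
    biomarker range tables, and runs in silico drug trials with pore-block
    IC50/Hill drug models and rule-based classification of arrhythmic
    phenotypes (early afterdepolarizations, repolarization failure, irregular
    rhythm, quiescence, residual activity).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
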
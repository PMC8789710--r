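Package: pvloop
Title: Invasive Left Ventricular Pressure-Volume Loop Analysis and
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for invasive left-ventricular
    pressure-volume (PV) loop recordings as acquired with conductance
    catheters in patients with severe aortic stenosis before and after
    transcatheter valve replacement: cardiac-cycle segmentation with
    extrasystole exclusion, the complete hemodynamic index battery
    (stroke work, preload recruitable stroke work, end-systolic and
    end-diastolic elastance, relaxation constant Tau, arterial elastance,
    valvulo-arterial impedance, ventricular-arterial coupling),
    40-point loop canonicalization and averaging, and exact nonparametric
    paired cohort statistics. Includes a time-varying-elastance
    cardiovascular simulator with a three-element Windkessel afterload and
    a quadratic-orifice stenotic valve that generates synthetic
    recordings with known ground truth for validating every estimator by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
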
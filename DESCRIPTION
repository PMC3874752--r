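Package: laphase
Title: Phasic Left Atrial Volumetry and Its Diagnostic Evaluation Against
    Elevated LV Filling Pressure
Version: 0.1.0
Authors@R:
    person("Avery", "Kestrel", email = "avery.kestrel@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for phasic left atrial (LA)
    quantitation from cine cardiac imaging. Computes biplane area-length LA
    volumes (0.85*A1*A2/L), extracts the phasic volume triple (LAVmax,
    LAVac, LAVmin) by both single-phase (valve-event frame) and multi-phase
    (time-volume curve landmark) methods, and derives total, passive and
    contractile emptying fractions. Includes a synthetic-cohort generator
    with LVEDP-linked ground-truth volumes and physiologic time-volume
    curve morphology, plus the diagnostic statistics used to evaluate LA
    indices against dichotomized LV end-diastolic pressure: empirical ROC
    with DeLong inference, Youden-optimal cutoffs, group comparisons,
    Bland-Altman method agreement and Lin's concordance correlation for
    observer variability. A command-line pipeline chains simulation,
    quantitation and evaluation into a reproducible study report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
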
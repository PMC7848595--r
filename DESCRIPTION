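Package: emcell
Title: Coupled Electro-Mechanical Simulation of Human Ventricular Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Strongly coupled single-cell models of human ventricular
    electrophysiology (ToR-ORd and the Dutta-modified ORd) and active
    contraction (Land 2017 crossbridge model), linked bidirectionally through
    dynamic calcium-troponin C buffering. Provides pacing and steady-state
    protocols with a stiff solver, action potential, calcium transient and
    active tension biomarkers, detectors for early afterdepolarisations,
    aftercontractions and contractility escapes, a pore-block in-silico drug
    trial engine with dose-response Hill fitting, recalibration of the
    contraction model to human twitch data, and transmural heterogeneity
    analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
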
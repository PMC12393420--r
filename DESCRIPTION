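Package: dyrknet
Title: Logic-Based ODE Modeling of DYRK1A-Mediated Cardiomyocyte Cell-Cycle Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates signaling and gene-regulatory networks as logic-based
    ordinary differential equations built from normalized Hill activation
    functions with continuous AND/OR gate algebra. Ships a curated network of
    DYRK1A-mediated cell-cycle quiescence in cardiomyocytes (DREAM complex
    assembly, RB1/E2F control of DNA replication) together with in-silico
    perturbation protocols (graded knockdown, overexpression), a literature
    direction-validation harness, a knockdown concentration-response analysis
    with EC50/IC50 extraction, a full single-node knockdown screen, and
    synthetic network generators with analytically known steady states for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
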
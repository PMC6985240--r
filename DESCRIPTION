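Package: qpopr
Title: Quadratic Phenotypic Optimization for Combinatorial Drug Screening
Version: 0.1.0
Authors@R: person("QPOPR", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Design and analysis toolkit for small-sample combinatorial drug
    screens. Constructs orthogonal array composite designs (OACD) for panels
    of drugs on a coded dose grid, fits a second-order polynomial (quadratic)
    viability surface to normalized readouts, exhaustively ranks every k-drug
    combination by predicted viability, and provides follow-up
    pharmacodynamics: four-parameter logistic dose-response fitting,
    median-effect analysis, Chou-Talalay combination indices and two-drug
    response surface maps. Includes a synthetic-data generator with known
    ground truth and a command-line interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
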
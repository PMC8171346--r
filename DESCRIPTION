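Package: tnckit
Title: Sarcomere Kinetics and Conformational-Ensemble Analytics for Cardiac Troponin C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for multi-scale studies of cardiac
    troponin C (cTnC) variants. Implements a three-state sarcomere kinetic
    model with steady-state force-pCa and tension-redevelopment (kTR)
    prediction and joint fitting, Hill regression of force-pCa data,
    conformational-ensemble analytics (interhelical angles, open-state
    fractions, RMSF, contact maps, Calpha PCA and one-dimensional free-energy
    landscapes), a simplified local mutational frustration index, NMR
    observable calculators (chemical shift perturbation, amide temperature
    coefficients, relaxation-rate fitting, CPMG R2eff and exchange-regime
    classification, titration Kd fits), and CD/SAXS descriptors (mean residue
    ellipticity, thermal-unfolding fits, Kratky and dimensionless Kratky
    transforms with a Guinier helper). Seeded synthetic-data generators
    emulate every input class so the full chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
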
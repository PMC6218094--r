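Package: qcredox
Title: Calibrated Quantum-Chemistry Prediction of Biochemical Redox Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning per-conformer electronic energies of metabolites into
    biochemical standard transformed reduction potentials E'm at specified pH, ionic
    strength and a 1 mM reactant standard state. Implements Boltzmann conformer-energy
    averaging referenced to molecular hydrogen, protonation-species ladders from pKa
    tables, the extended Debye-Huckel correction and the Alberty-Legendre transform,
    per-category two-parameter linear calibration against experimental potentials,
    an alternative MACCS-key reaction-fingerprint Lasso predictor, cross-method
    z-score detection of suspect experimental values, rule-based enumeration of
    candidate redox pairs from functional-group vectors, and analyses of couple
    compatibility with physiological electron carriers such as NAD(P).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
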
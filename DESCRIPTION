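Package: etbridge
Title: Interface Mapping and Electron-Transfer Pathway Analysis for Redox
    Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising electron-transfer complexes between
    redox proteins from solution NMR and scattering data. Implements
    chemical-shift-perturbation (CSP) interface mapping with SD-based
    classification and contiguity-based interface calling, Morrison
    tight-binding and one-electron Nernst titration fits, a bell-shaped
    pH-activity model with an acidic shoulder equilibrium, pseudocontact-shift
    evaluation for anisotropic paramagnetic centres, a Beratan-Onuchic
    Pathways electron-tunneling coupling calculator with max-product path
    search, coupling-based ranking and restraint-driven filtering of docking
    pose ensembles with HADDOCK-style restraint generation, and structure
    ensemble and SAXS descriptors (Kabsch superposition, per-residue RMSD,
    pair-distance distributions, Guinier and Kratky analysis, Shrake-Rupley
    SASA, sequence mass and isoelectric point). Seeded synthetic-data
    generators emulate every input so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
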
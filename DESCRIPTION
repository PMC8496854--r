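Package: moietherm
Title: Moiety-Based Prediction of Biochemical Reaction Gibbs Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated, stereochemistry-aware fragmentation of metabolite
    structures into atom-environment moieties, Bayesian ridge regression of
    moiety Gibbs energy contributions with predictive uncertainty, protonation
    (pseudoisomer) corrections for pH and ionic strength via the inverse
    Legendre transform, end-to-end standard transformed Gibbs energy
    prediction for biochemical reactions (including reactions with novel
    metabolites given as InChI strings), and thermodynamic directionality
    classification of reaction rules for de novo pathway design. Structure
    parsing and fragment canonicalization are delegated to RDKit through a
    bundled Python worker.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the rdkit package importable
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
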
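Package: rxnaug
Title: Virtual Data Augmentation for Coupling-Reaction Prediction Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Curation and augmentation of cross-coupling reaction SMILES
    datasets for sequence-to-sequence reaction prediction. Generates
    chemically valid virtual ("fake") reactions by substituting equivalent
    leaving-group functional groups (halogen, boron, silicon, Grignard
    halide) in reactants while leaving the product untouched, screens
    corpora against the five coupling-reaction templates (Hiyama, Suzuki,
    Kumada, Buchwald-Hartwig, Chan-Lam), performs canonicalization,
    deduplication, train-only augmentation with leakage guards, 8:1:1 and
    k-fold splitting, tokenized parallel-corpus export, and a four-category
    classification of wrong product predictions. Molecule handling is
    backed by Open Babel through ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
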
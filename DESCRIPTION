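Package: procleave
Title: Prediction of C-Terminal Antigen Processing from Immunopeptidomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds cleavage-site training data from mass-spectrometry eluted
    MHC ligands and their source proteins, encodes seven-residue cleavage
    windows (P4-P3' in Schechter-Berger nomenclature) with physicochemical
    amino-acid descriptors, and trains a shallow feed-forward neural network
    to predict the probability that a peptide C-terminus is generated by
    antigen processing. Includes decoy negative sampling adjacent to observed
    cleavage sites, standard classification metrics (PPV, TPR, MCC, ROC AUC),
    immunogenicity benchmark curation, whole-protein scanning, and a
    deterministic synthetic-data generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
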
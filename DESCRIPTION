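Package: misscan
Title: Missing-Residue Classification and Disorder-Score Analysis for
    Experimental Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies protein residues as modeled, hard missing or soft
    missing from the presence of C-alpha coordinates across grouped
    experimental structure entries, segments hard-missing runs into short
    and long disordered regions, and relates the classes to AlphaFold pLDDT
    confidence and IUPred disorder score tracks through correlation,
    quadrant and composition analyses. Provides pLDDT and IUPred threshold
    baselines and a compact LSTM per-residue labeler, region-length
    stratified precision/recall/F1 evaluation, a modeled-ratio screen for
    prioritizing unsolved sequences, and a seeded synthetic-data generator
    so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
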
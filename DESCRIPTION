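Package: itsstruct
Title: Sequence-Structure Analysis of Nuclear Ribosomal ITS Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint sequence and secondary-structure analysis of the nuclear
    ribosomal internal transcribed spacers (ITS1, 5.8S, ITS2). Provides motif-
    anchored region annotation, base-pair maximization / stacking dynamic
    programming folding with an optional ViennaRNA backend, template-based
    homology modeling of the canonical four-helix ITS2 fold, synchronized
    sequence-structure alignment in a 12-state alphabet, classification of
    compensatory (CBC), hemi-compensatory (hCBC) and non-structural (Nst) base
    changes, per-group consensus structures and helix statistics, conserved-
    motif and pseudogene screening, nucleotide diversity and genetic distance
    tables, distance-based trees with bootstrap support, and a structure-aware
    simulator of ITS families with a planted event log for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
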
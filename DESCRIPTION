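Package: coevomap
Title: Mutual Information Coevolution Networks from Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes corrected mutual information (MI) z-scores between
    residue positions of a protein multiple sequence alignment, using
    sequence weighting, additive low-count correction, the average product
    correction (APC) of background signal and a column-permutation null.
    Builds residue coevolution networks from significant pairs, per-residue
    Kullback-Leibler conservation, cumulative MI and structural proximity MI,
    maps alignment positions onto a PDB chain by Smith-Waterman local
    alignment, and renders circular (circos-style) and network summaries.
    Includes a synthetic-alignment generator with planted covarying column
    pairs and toy structure files for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
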
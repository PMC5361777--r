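Package: tickPI
Title: Comparative Protease Inhibitor Repertoire Analysis for Tick Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing protease inhibitor (PI) repertoires from tick
    transcriptome and database protein sets. Assigns sequences to MEROPS-style
    inhibitor families by diagnostic motif or by identity to annotated reference
    members, collapses redundant sequences within a species and family at a 95
    percent identity threshold, builds condition-wise presence/absence repertoire
    matrices (sex, feeding state, tissue), rolls family counts up to protease
    catalytic types, and screens non-redundant PIs for cross-species homologs at
    50 percent identity or better. Pairwise global and local protein alignment
    with affine gaps is implemented in compiled code. A synthetic-data generator
    plants redundancy clusters, family motifs, homolog pairs and library
    memberships with machine-readable ground truth so every stage can be verified
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
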
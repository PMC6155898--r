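Package: tdcsig
Title: Signature-Motif Discrimination of Plant Tryptophan and Tyrosine
    Decarboxylases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate plant tryptophan decarboxylases (TDC)
    from tyrosine/DOPA decarboxylases (TYDC) by short degenerate signature
    motifs. Implements a progressive multiple sequence aligner with affine
    gap penalties, automated discovery of group-discriminative conserved
    motifs from class-labeled alignments, vote-based family classification
    of query sequences, neighbor-joining dendrograms with bootstrap
    supports on Dayhoff-corrected distances, and the multiple reaction
    monitoring (MRM) transition arithmetic for tryptamine and its
    N-methyl derivatives, including indole-ring deuterium (d5) labeling.
    Ships the curated catalog of 42 plant TDC/TYDC accessions and the four
    diagnostic signature pairs, plus a synthetic family generator with
    planted motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
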
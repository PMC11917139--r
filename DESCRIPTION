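Package: kcapture
Title: Alignment-Free Capture of Conserved Short Linear Motifs in
    Disordered Protein Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects conserved short linear motifs (SLiMs) in sets of
    related protein sequences without a multiple sequence alignment.
    Sequences are decomposed into overlapping k-mers which are compared
    across all sequence pairs by a physicochemical similarity score
    derived from the Grantham amino-acid distance matrix; reciprocal
    best-matching k-mers are counted and weighted by the per-length
    search space to rank consensus k-mers comparably across k. Includes
    a post-processing step that extends top-ranked motif regions, site-
    and residue-level benchmark metrics against annotated motif tables,
    pLDDT-based segmentation of intrinsically disordered regions with
    proteome-scale motif filters, and a synthetic ortholog-set generator
    with planted motifs for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
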
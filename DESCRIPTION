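Package: vnarseq
Title: IgNAR Germline Mining and vNAR Immune Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the immunoglobulin new antigen receptor
    (IgNAR) system of cartilaginous fish: recombination-signal-sequence (RSS)
    scanning and germline V/D/J/C cluster mining from genome assemblies,
    V(D)J annotation of single-domain (vNAR) repertoire reads with CDR3
    extraction, repertoire diversity and clonality statistics
    (Shannon-Wiener index, Wu-Kabat variability, V-J pairing, clonotype
    overlap and tracking), cysteine-pattern vNAR type classification, and a
    fully seeded V(D)J recombination read simulator providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, ImmunoOncology, Software
RoxygenNote: 7.3.3
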
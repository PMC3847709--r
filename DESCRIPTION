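Package: venomscan
Title: Venom-Gland Transcriptome Assembly and Similarity-Network Toxin
    Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end annotation of venom-gland transcriptomes at desk
    scale: a synthetic transcriptome and read-library generator with
    ground-truth labels, a greedy overlap-consensus mini-assembler with
    read-to-contig abundance mapping, six-frame ORF discovery with a
    rule-based signal-peptide and cysteine-scaffold screen, all-vs-all
    protein similarity with Karlin-Altschul E-values, reciprocal-best-hit
    confirmation and greedy non-redundant clustering, sequence-similarity
    networks with connected-component family grouping and
    Cytoscape-compatible export, a keyword plus reciprocal-best-hit toxin
    annotation workflow with stringency filters, novel-secreted-candidate
    detection, abundance ranking with cumulative coverage curves,
    polycistronic sarafotoxin precursor parsing, and a lightweight pairwise
    Nei-Gojobori dN/dS screen for diversifying selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
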
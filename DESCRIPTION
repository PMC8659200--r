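Package: cycloMiner
Title: Transporter-Guided Genome Mining for Head-to-Tail Cyclized Bacteriocins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for head-to-tail cyclized (circular) bacteriocin
    biosynthetic gene clusters in annotated bacterial genomes. Characterized
    bacteriocin transporter proteins seed a Smith-Waterman homology search;
    genome neighborhoods around transporter hits are screened with a
    co-occurrence filter requiring a precursor peptide, a SpoIIM (DUF95)
    membrane protein and at least one transporter. Candidate precursors are
    profiled physicochemically (Kyte-Doolittle GRAVY, Henderson-Hasselbalch net
    charge and isoelectric point, cyclic or linear) and classified into the
    cationic (subgroup i) and neutral-hydrophobic (subgroup ii) classes, grouped
    by a thresholded sequence similarity network, summarized per group with
    progressive multiple alignments, sequence-logo matrices and leader-peptide
    cleavage-site transfer from characterized anchors, and related by a
    neighbor-joining tree on alignment distances. A synthetic-genome simulator
    with implanted, ground-truthed clusters and decoys makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
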
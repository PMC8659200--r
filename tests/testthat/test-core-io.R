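writeTmpGenome <- function(fasta_lines, gff_lines = NULL) {
    fa <- tempfile(fileext = ".fna")
    writeLines(fasta_lines, fa)
    gff <- NULL
    if (!is.null(gff_lines)) {
        gff <- tempfile(fileext = ".gff3")
        writeLines(gff_lines, gff)
    }
    list(fa = fa, gff = gff)
}

test_that("FASTA without annotation loads with zero features", {
    p <- writeTmpGenome(c(">c1", "ATGAAATAA"))
    g <- loadAnnotatedGenome(p$fa)
    expect_s4_class(g, "GenomeRecord")
    expect_equal(length(features(g)), 0L)
    expect_equal(as.character(contigs(g)[["c1"]]), "ATGAAATAA")
})

test_that("CDS features are translated under the bacterial code", {
    p <- writeTmpGenome(c(">c1", "ATGAAATAA"),
                        c("##gff-version 3",
                          "c1\ttest\tCDS\t1\t9\t.\t+\t0\tID=p1"))
    g <- loadAnnotatedGenome(p$fa, p$gff)
    md <- S4Vectors::mcols(features(g))
    expect_equal(as.character(md$protein), "MK")   # stop trimmed
    expect_false(md$premature_stop)
    # alternative initiator codons translate to M
    p2 <- writeTmpGenome(c(">c1", "TTGAAATAA"),
                         c("##gff-version 3",
                           "c1\ttest\tCDS\t1\t9\t.\t+\t0\tID=p1"))
    g2 <- loadAnnotatedGenome(p2$fa, p2$gff)
    expect_equal(as.character(S4Vectors::mcols(features(g2))$protein), "MK")
})

test_that("a GFF3 naming an absent contig is a cross-reference error", {
    p <- writeTmpGenome(c(">c1", "ATGAAATAA"),
                        c("##gff-version 3",
                          "nope\ttest\tCDS\t1\t9\t.\t+\t0\tID=p1"))
    expect_error(loadAnnotatedGenome(p$fa, p$gff), "absent from FASTA")
})

test_that("forward and reverse-complement CDS translations agree", {
    set.seed(301)
    cfg <- simConfig(seed = 301, genome_id = "rc", n_background = 4L)
    g <- generateGenome(cfg)$genome
    ft <- features(g)
    md <- S4Vectors::mcols(ft)
    dna <- as.character(contigs(g)[[1]])
    for (i in seq_along(ft)) {
        cds <- substr(dna, GenomicRanges::start(ft)[i],
                      GenomicRanges::end(ft)[i])
        if (as.character(GenomicRanges::strand(ft))[i] == "-")
            cds <- cycloMiner:::.revcomp(cds)
        expect_equal(cycloMiner:::.translateCDS(cds)$protein,
                     as.character(md$protein[i]))
    }
})

test_that("internal stop codons flag the CDS and drop it from the proteome", {
    p <- writeTmpGenome(c(">c1", "ATGTAAAAATAA"),
                        c("##gff-version 3",
                          "c1\ttest\tCDS\t1\t12\t.\t+\t0\tID=bad"))
    g <- loadAnnotatedGenome(p$fa, p$gff)
    md <- S4Vectors::mcols(features(g))
    expect_true(md$premature_stop)
    expect_equal(length(genomeProteome(g)), 0L)
})

test_that("genome round-trip preserves contigs and coordinates exactly", {
    cfg <- simConfig(seed = 302, genome_id = "rt", n_background = 5L,
                     clusters = list(clusterSpec("uberolysin",
                                                 identity = 80)))
    g <- generateGenome(cfg)$genome
    fa <- tempfile(fileext = ".fna"); gff <- tempfile(fileext = ".gff3")
    writeGenome(g, fa, gff)
    g2 <- loadAnnotatedGenome(fa, gff, genome_id = genomeId(g))
    expect_equal(as.character(contigs(g2)), as.character(contigs(g)))
    expect_equal(GenomicRanges::start(features(g2)),
                 GenomicRanges::start(features(g)))
    expect_equal(GenomicRanges::end(features(g2)),
                 GenomicRanges::end(features(g)))
    expect_equal(as.character(GenomicRanges::strand(features(g2))),
                 as.character(GenomicRanges::strand(features(g))))
    expect_equal(as.character(S4Vectors::mcols(features(g2))$protein),
                 as.character(S4Vectors::mcols(features(g))$protein))
})

test_that("edge lists round-trip through the written TSVs", {
    seqs <- c(n1 = "MKWLFGWWLFMKWLF", n2 = "MKWLFGWWLFMKWLF",
              n3 = "MKWLFGWWLAMKWLF", n4 = "GAVSTGAVSTGAVST")
    nodes <- dedupeSequences(seqs)
    graph <- buildSSN(nodes, identity_threshold_pct = 50, min_score = 20)
    prefix <- tempfile()
    writeEdgeList(graph, prefix)
    back <- readEdgeList(paste0(prefix, "_edges.tsv"))
    expect_equal(nrow(back), nrow(ssnEdges(graph)))
    expect_setequal(paste(back$node_a, back$node_b),
                    paste(ssnEdges(graph)$node_a, ssnEdges(graph)$node_b))
    nodeTab <- read.delim(paste0(prefix, "_nodes.tsv"))
    expect_equal(nrow(nodeTab), nrow(nodes))

    # empty graph: header-only files
    g0 <- buildSSN(dedupeSequences(c(a = "MKWLF")))
    p0 <- tempfile()
    writeEdgeList(g0, p0)
    expect_equal(nrow(readEdgeList(paste0(p0, "_edges.tsv"))), 0L)
})

test_that("result tables dedupe across genomes and regenerate byte-identically", {
    # two genomes carrying the identical precursor
    cfg1 <- simConfig(seed = 303, genome_id = "gA", n_background = 3L)
    cfg2 <- simConfig(seed = 304, genome_id = "gB", n_background = 3L)
    mkBgc <- function(gid, seqc) {
        methods::new("CandidateBGC", genomeId = gid, contigId = "c1",
                     anchorId = "t1", span = c(1L, 1000L),
                     genes = data.frame(id = c("t1", "s1"),
                                        start = c(1L, 500L),
                                        end = c(400L, 900L),
                                        strand = "+", product = "x",
                                        role = c("transporter", "spoIIM"),
                                        role_score = 100, role_identity = 80,
                                        stringsAsFactors = FALSE),
                     precursors = data.frame(
                         id = "p1", sequence = seqc, length = nchar(seqc),
                         start = 10L, end = 10L + 3L * nchar(seqc),
                         strand = "+", origin = "annotated_cds",
                         seed_identity_pct = 80, support = "homology",
                         gravy = 1, net_charge = 3, subgroup = "i",
                         stringsAsFactors = FALSE),
                     flags = c(yip1 = FALSE, transposase = FALSE,
                               peptidase = FALSE),
                     verdict = "pass", failReasons = character())
    }
    seqc <- "MKAKAKWLFKAWLGAVLIFWATSLV"
    bgcs <- list(mkBgc("gA", seqc), mkBgc("gB", seqc))
    nodes <- dedupeSequences(c(gA_p1 = seqc, gB_p1 = seqc))
    graph <- buildSSN(nodes)
    groups <- assignGroups(graph)
    profiles <- physchemProfile(setNames(nodes$sequence, nodes$id))
    d1 <- tempfile(); d2 <- tempfile()
    writeResultsTables(bgcs, nodes, groups, profiles, d1)
    writeResultsTables(bgcs, nodes, groups, profiles, d2)
    expect_identical(readLines(file.path(d1, "hits.tsv")),
                     readLines(file.path(d2, "hits.tsv")))
    grp <- read.delim(file.path(d1, "groups.tsv"),
                      colClasses = c("character", "integer", "integer"))
    sing <- grp[grp$group_id == "singletons", ]
    expect_equal(sing$n_unique, 1L)    # one unique sequence
    expect_equal(sing$n_genomes, 2L)   # shared by two genomes

    # zero candidates: header-only tables
    d0 <- tempfile()
    writeResultsTables(list(), nodes[0, ], groups[0, ], profiles[0, ], d0)
    expect_equal(nrow(read.delim(file.path(d0, "hits.tsv"))), 0L)

    # inconsistent cross-references are a validation error
    expect_error(writeResultsTables(bgcs, nodes, groups[0, ], profiles, d0),
                 "validation error")
})
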
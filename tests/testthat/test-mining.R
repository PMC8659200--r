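seedsFixture <- defaultSeedSet()

test_that("window extraction truncates at contig ends and honors k", {
    cfg <- simConfig(seed = 401, genome_id = "wx", n_background = 21L)
    g <- generateGenome(cfg)$genome
    ids <- as.character(S4Vectors::mcols(features(g))$protein_id)
    w <- extractWindow(g, ids[11], k = 10L)
    expect_equal(nrow(w$genes), 21L)
    expect_equal(substr(as.character(contigs(g)[[1]]), w$span[1], w$span[2]),
                 w$dna)
    wEdge <- extractWindow(g, ids[1], k = 10L)
    expect_equal(nrow(wEdge$genes), 11L)   # truncated on the left
    wSmall <- extractWindow(g, ids[11], k = 1L)
    expect_equal(nrow(wSmall$genes), 3L)
    expect_error(extractWindow(g, "missing"), "anchor not found")
})

test_that("single-gene contigs give single-gene windows", {
    cfg <- simConfig(seed = 402, genome_id = "w1", n_background = 1L)
    g <- generateGenome(cfg)$genome
    id <- as.character(S4Vectors::mcols(features(g))$protein_id)[1]
    w <- extractWindow(g, id, k = 10L)
    expect_equal(nrow(w$genes), 1L)
})

test_that("ORF scanning finds exactly the hand-derived ORF", {
    w <- mkWindow(paste(rep("A", 300), collapse = ""))
    expect_equal(nrow(scanOrfs(w, 25, 150)), 0L)   # no stop closes a frame
    w2 <- mkWindow("ATGAAATGTTAA")
    orfs <- scanOrfs(w2, 1, 10)
    expect_equal(nrow(orfs), 1L)
    expect_equal(orfs$sequence, "MKC")
    expect_equal(orfs$start, 1L)
    expect_equal(orfs$end, 12L)        # stop codon included
    expect_equal(orfs$strand, "+")
})

test_that("ORF scanning is invariant under reverse complement", {
    set.seed(403)
    dna <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    L <- nchar(dna)
    fwd <- scanOrfs(mkWindow(dna), 20, 150)
    rev <- scanOrfs(mkWindow(cycloMiner:::.revcomp(dna)), 20, 150)
    mapBack <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                          strand = ifelse(rev$strand == "+", "-", "+"),
                          sequence = rev$sequence)
    key <- function(d) sort(paste(d$start, d$end, d$strand, d$sequence))
    expect_equal(key(fwd), key(mapBack))
})

test_that("ORFs inside annotated CDS are suppressed", {
    cds <- cycloMiner:::.reverseTranslate  # not exercised here; build by hand
    dna <- "ATGAAATGTTAA"
    genes <- data.frame(id = "g1", start = 1L, end = 12L, strand = "+",
                        feature_kind = "CDS", product = "x",
                        protein = "MKC", premature_stop = FALSE,
                        stringsAsFactors = FALSE)
    w <- mkWindow(dna, genes)
    expect_equal(nrow(scanOrfs(w, 1, 10)), 0L)
    # same ORF with the annotation on the other strand is kept
    genes$strand <- "-"
    expect_equal(nrow(scanOrfs(mkWindow(dna, genes), 1, 10,
                               suppress_shadow = FALSE)), 1L)
})

test_that("a transporter-only window fails with both missing roles", {
    cfg <- simConfig(seed = 404, genome_id = "d0", n_background = 6L,
                     clusters = list(clusterSpec("pumilarin", identity = 80,
                                                 omit_role = "precursor",
                                                 include_spoiim = FALSE)))
    g <- generateGenome(cfg)$genome
    res <- mineGenome(g, seedsFixture)
    expect_equal(res$n_windows, 1L)
    b <- res$bgcs[[1]]
    expect_equal(verdict(b), "fail")
    expect_setequal(failReasons(b), c("no_precursor", "no_spoiim"))
})

test_that("implanted clusters at 70% identity pass; decoys fail", {
    cfgPass <- simConfig(seed = 405, genome_id = "ok",
                         clusters = list(clusterSpec("enterocin_AS-48",
                                                     identity = 70)))
    simPass <- generateGenome(cfgPass)
    res <- mineGenome(simPass$genome, seedsFixture)
    pass <- Filter(function(b) verdict(b) == "pass", res$bgcs)
    expect_equal(length(pass), 1L)
    b <- pass[[1]]
    # window span covers every implanted cluster gene
    man <- simPass$manifest
    expect_true(all(man$start >= b@span[1] & man$end <= b@span[2]))
    # the implanted precursor is recovered by homology at ~70% seed identity
    prec <- precursors(b)
    hom <- prec[prec$support == "homology", ]
    expect_gte(nrow(hom), 1L)
    expect_true(any(hom$sequence %in% man$sequence[man$role == "precursor"]))

    cfgDecoy <- simConfig(seed = 406, genome_id = "dk",
                          clusters = list(clusterSpec("enterocin_AS-48",
                                                      identity = 70,
                                                      omit_role = "spoIIM")))
    resD <- mineGenome(generateGenome(cfgDecoy)$genome, seedsFixture)
    expect_true(all(vapply(resD$bgcs, verdict, character(1)) == "fail"))
    expect_true(any(vapply(resD$bgcs, function(b)
        "no_spoiim" %in% failReasons(b), logical(1))))
})

test_that("unannotated precursors are recovered by ORF scan at exact coordinates", {
    cfg <- simConfig(seed = 407, genome_id = "un",
                     clusters = list(clusterSpec("uberolysin", identity = 75,
                                                 precursor_annotation =
                                                     "unannotated")))
    sim <- generateGenome(cfg)
    man <- sim$manifest
    precTruth <- man[man$role == "precursor", ]
    expect_false(precTruth$annotated)
    res <- mineGenome(sim$genome, seedsFixture)
    pass <- Filter(function(b) verdict(b) == "pass", res$bgcs)
    expect_equal(length(pass), 1L)
    prec <- precursors(pass[[1]])
    prec <- prec[prec$support == "homology", ]
    hit <- prec[prec$sequence == precTruth$sequence, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$origin, "orf_scan")
    expect_equal(hit$start, precTruth$start)
    expect_equal(hit$end, precTruth$end)
    expect_equal(hit$strand, precTruth$strand)
})

test_that("multi-copy precursors are all reported within one candidate", {
    cfg <- simConfig(seed = 408, genome_id = "mc",
                     clusters = list(clusterSpec("amylocyclicin",
                                                 identity = 80,
                                                 n_precursors = 3L)))
    sim <- generateGenome(cfg)
    res <- mineGenome(sim$genome, seedsFixture)
    pass <- Filter(function(b) verdict(b) == "pass", res$bgcs)
    expect_equal(length(pass), 1L)
    hom <- precursors(pass[[1]])
    hom <- hom[hom$support == "homology", ]
    expect_equal(nrow(hom), 3L)
})

test_that("accessory genes set flags without affecting the verdict", {
    cfg <- simConfig(seed = 409, genome_id = "ac",
                     clusters = list(clusterSpec("gassericin_A",
                                                 identity = 80,
                                                 include_yip1 = TRUE,
                                                 include_transposase = TRUE,
                                                 include_peptidase = TRUE)))
    res <- mineGenome(generateGenome(cfg)$genome, seedsFixture)
    pass <- Filter(function(b) verdict(b) == "pass", res$bgcs)
    expect_equal(length(pass), 1L)
    expect_true(all(pass[[1]]@flags[c("yip1", "transposase", "peptidase")]))
})

test_that("an empty seed role set is a configuration error", {
    info <- as.data.frame(seedInfo(seedsFixture))
    keep <- info$role != "precursor"
    noPrec <- SeedSet(setNames(as.character(seedSequences(seedsFixture))[keep],
                               info$id[keep]),
                      info[keep, ])
    w <- mkWindow("ATGAAATGTTAA")
    expect_error(classifyRoles(w, noPrec), "no precursor entries")
})
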
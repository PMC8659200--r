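test_that("mutation hits its identity target and is reproducible", {
    set.seed(801)
    p <- randProtein(100)
    expect_identical(as.character(mutateToIdentity(p, 100)), p)
    for (trial in 1:20) {
        m <- mutateToIdentity(p, 50)
        al <- alignGlobal(p, as.character(m))
        realized <- 100 * al$n_identical / al$n_aligned_columns
        expect_gte(realized, 47)
        expect_lte(realized, 53)
        expect_equal(attr(m, "realized_identity"), realized)
    }
    set.seed(99); a <- mutateToIdentity(p, 60)
    set.seed(99); b <- mutateToIdentity(p, 60)
    expect_identical(a, b)
    # nested ladders keep lower-divergence members inside higher ones
    ord <- sample.int(100)
    m90 <- as.character(mutateToIdentity(p, 90, ord))
    m60 <- as.character(mutateToIdentity(p, 60, ord))
    al <- alignGlobal(m90, m60)
    expect_gte(100 * al$n_identical / al$n_aligned_columns, 65)
})

test_that("very short sequences warn when the target is unreachable", {
    expect_warning(mutateToIdentity("MK", 75), "realized identity")
})

test_that("cluster-free genomes mine to nothing", {
    cfg <- simConfig(seed = 802, genome_id = "neg", n_background = 8L)
    sim <- generateGenome(cfg)
    expect_equal(nrow(sim$manifest), 0L)
    res <- mineGenome(sim$genome, defaultSeedSet())
    expect_equal(length(Filter(function(b) verdict(b) == "pass", res$bgcs)),
                 0L)
})

test_that("emitted cluster CDS translate back to the mutated proteins", {
    cfg <- simConfig(seed = 803, genome_id = "rtp",
                     clusters = list(clusterSpec("garvicin_ML", identity = 65,
                                                 n_transporters = 2L,
                                                 include_peptidase = TRUE)))
    sim <- generateGenome(cfg)
    dna <- as.character(contigs(sim$genome)[[1]])
    man <- sim$manifest
    for (i in seq_len(nrow(man))) {
        cds <- substr(dna, man$start[i], man$end[i])
        if (man$strand[i] == "-") cds <- cycloMiner:::.revcomp(cds)
        expect_equal(cycloMiner:::.translateCDS(cds)$protein,
                     man$sequence[i], info = man$id[i])
    }
    # realized identities stay within the tolerance band of the target
    offTarget <- abs(man$realized_identity - man$target_identity)
    expect_true(all(offTarget <= 3))
})

test_that("manifest coordinates agree with the emitted GFF3", {
    od <- tempfile()
    cfg <- simConfig(seed = 804, genome_id = "gsync",
                     clusters = list(clusterSpec("BacA", identity = 75)))
    sim <- generateGenome(cfg, out_dir = od)
    gff <- readLines(file.path(od, "gsync.gff3"))
    man <- read.delim(file.path(od, "gsync_manifest.tsv"))
    for (i in seq_len(nrow(man))) {
        if (!man$annotated[i]) next
        row <- grep(paste0("ID=", man$id[i], ";"), gff, value = TRUE)
        expect_equal(length(row), 1L)
        f <- strsplit(row, "\t")[[1]]
        expect_equal(as.integer(f[4]), man$start[i])
        expect_equal(as.integer(f[5]), man$end[i])
        expect_equal(f[7], man$strand[i])
    }
    # reloading the emitted files reproduces the in-memory genome
    g2 <- loadAnnotatedGenome(file.path(od, "gsync.fna"),
                              file.path(od, "gsync.gff3"))
    expect_equal(as.character(contigs(g2)[[1]]),
                 as.character(contigs(sim$genome)[[1]]))
})

test_that("generation is fully deterministic under a fixed seed", {
    cfg <- simConfig(seed = 805, genome_id = "det",
                     clusters = list(clusterSpec("paracyclicin",
                                                 identity = 70)))
    s1 <- generateGenome(cfg)
    s2 <- generateGenome(cfg)
    expect_identical(as.character(contigs(s1$genome)),
                     as.character(contigs(s2$genome)))
    expect_identical(s1$manifest, s2$manifest)
})

test_that("architectures needing an absent role are a configuration error", {
    seeds <- defaultSeedSet()
    info <- as.data.frame(seedInfo(seeds))
    keep <- info$role != "yip1"
    noYip <- SeedSet(setNames(as.character(seedSequences(seeds))[keep],
                              info$id[keep]), info[keep, ])
    cfg <- simConfig(seed = 806, genome_id = "bad", seeds = noYip,
                     clusters = list(clusterSpec("BacA", include_yip1 = TRUE)))
    expect_error(generateGenome(cfg), "no entry for role 'yip1'")
})

test_that("the benchmark set realizes its stated composition", {
    bench <- simulateBenchmarkSet(808)
    expect_equal(length(bench$genomes), 20L)
    expect_equal(length(bench$truth$complete), 6L)
    expect_equal(length(bench$truth$decoy), 4L)
    man <- bench$manifest
    expect_setequal(unique(man$genome_id[grepl("^cluster", man$element)]),
                    bench$truth$complete)
    expect_setequal(unique(man$genome_id[grepl("^decoy", man$element)]),
                    bench$truth$decoy)
    omitted <- vapply(bench$truth$decoy, function(g)
        paste(sort(setdiff(c("precursor", "spoIIM", "transporter"),
                           man$role[man$genome_id == g])), collapse = ","),
        character(1))
    expect_setequal(unname(omitted), c("precursor", "precursor",
                                       "spoIIM", "spoIIM"))
})
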
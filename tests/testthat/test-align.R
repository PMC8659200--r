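test_that("self-alignment gives full identity and coverage", {
    set.seed(101)
    for (len in c(1, 5, 30, 120)) {
        s <- randProtein(len)
        al <- alignLocal(s, s)
        expect_equal(al$identity_pct, 100)
        expect_equal(al$query_coverage, 1)
        expect_equal(al$subject_coverage, 1)
        expect_equal(al$n_identical, len)
    }
})

test_that("all-negative pair scores give the empty local alignment", {
    al <- alignLocal("AAAA", "CCCC")
    expect_equal(al$score, 0)
    expect_equal(al$n_aligned_columns, 0)
    expect_true(is.na(al$query_start))
    # cross-checked against the exhaustive enumeration
    p <- alignParams()
    expect_equal(bruteLocalAffine("AAAA", "CCCC", p$matrix), 0)
})

test_that("local scores match full-enumeration brute force at tiny lengths", {
    set.seed(102)
    p <- alignParams()
    for (trial in 1:200) {
        a <- randProtein(sample(1:4, 1))
        b <- randProtein(sample(1:4, 1))
        expect_equal(alignLocal(a, b, p)$score,
                     bruteLocalAffine(a, b, p$matrix),
                     info = paste(a, b))
    }
})

test_that("local scores match an independent aligner at length <= 6", {
    set.seed(103)
    data(BLOSUM62, package = "Biostrings", envir = environment())
    for (trial in 1:300) {
        a <- randProtein(sample(1:6, 1))
        b <- randProtein(sample(1:6, 1))
        ours <- alignLocal(a, b)$score
        # same gap cost model: L-long gap costs 10 + L under this pairing
        ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                             substitutionMatrix = BLOSUM62,
                                             gapOpening = 10, gapExtension = 1,
                                             scoreOnly = TRUE)
        expect_equal(ours, max(ref, 0), info = paste(a, b))
    }
})

test_that("global alignment charges end gaps and places gaps deterministically", {
    g <- alignGlobal("MKWVF", "MKVF")
    # M/K/V/F matches (5+5+4+6) minus one single-residue gap (11)
    expect_equal(g$score, 9)
    expect_equal(g$aligned_query, "MKWVF")
    expect_equal(g$aligned_subject, "MK-VF")
    g2 <- alignGlobal("MK", "MKAAAA")
    expect_equal(g2$score, 5 + 5 - (11 + 3 * 1))
})

test_that("score is symmetric in its arguments", {
    set.seed(104)
    for (trial in 1:40) {
        a <- randProtein(sample(3:40, 1))
        b <- randProtein(sample(3:40, 1))
        expect_equal(alignLocal(a, b)$score, alignLocal(b, a)$score)
    }
})

test_that("appending residues never decreases the optimal local score", {
    set.seed(105)
    for (trial in 1:25) {
        a <- randProtein(sample(5:30, 1))
        b <- randProtein(sample(5:30, 1))
        s0 <- alignLocal(a, b)$score
        expect_gte(alignLocal(paste0(a, randProtein(3)), b)$score, s0)
        expect_gte(alignLocal(a, paste0(b, randProtein(3)))$score, s0)
    }
})

test_that("X is scoreless against every residue", {
    p <- alignParams()
    expect_true(all(p$matrix["X", ] == 0))
    expect_true(all(p$matrix[, "X"] == 0))
    expect_equal(alignLocal("XXXX", "XXXX")$score, 0)
})

test_that("invalid input is rejected", {
    expect_error(alignLocal("", "MK"), "non-empty")
    expect_error(alignLocal("MKB", "MK"), "invalid residue")
    expect_error(alignParams(gap_open = 1, gap_extend = 2))
})

test_that("NCBI-format matrix files parse to the reference values", {
    path <- tempfile(fileext = ".txt")
    writeLines(c("# tiny excerpt in NCBI layout",
                 "   A  R  N  *",
                 "A  4 -1 -2 -4",
                 "R -1  5  0 -4",
                 "N -2  0  6 -4",
                 "* -4 -4 -4  1"), path)
    m <- readSubstitutionMatrix(path)
    expect_equal(dim(m), c(21L, 21L))
    expect_equal(m["A", "A"], 4)
    expect_equal(m["R", "N"], 0)
    expect_equal(m["A", "X"], 0)      # X padded in, scoreless
    expect_equal(m["A", "D"], 0)      # absent letters default to 0
})

test_that("proteome search applies thresholds and keeps best hit per pair", {
    set.seed(106)
    q <- c(seed1 = randProtein(60))
    prot <- c(hit = q[["seed1"]], other = randProtein(60))
    res <- searchProteome(q, prot,
                          thresholds = searchThresholds(min_raw_score = 30))
    expect_true("hit" %in% res$target_id)
    expect_equal(res$identity_pct[res$target_id == "hit"], 100)
    expect_equal(sum(res$target_id == "hit" & res$query_id == "seed1"), 1L)

    none <- searchProteome(q, prot,
                           thresholds = searchThresholds(min_identity_pct = 100,
                                                         min_raw_score = 1e6))
    expect_equal(nrow(none), 0L)

    expect_error(searchProteome(c(a = "MK", a = "MK"), prot), "duplicate")
})

test_that("identity uses aligned columns including internal gaps", {
    # forced internal gap: identical flanks, one extra residue in the query
    a <- "MKWLFGWWLFMKWLFGWWLF"
    b <- paste0(substr(a, 1, 10), "AAA", substr(a, 11, 20))
    al <- alignLocal(b, a)
    expect_equal(al$n_aligned_columns, 23)
    expect_equal(al$identity_pct, 100 * 20 / 23)
})
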
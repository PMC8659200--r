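test_that("exact-string deduplication sets multiplicity and first-seen ids", {
    same <- c(r1 = "MKWLF", r2 = "MKWLF", r3 = "MKWLF")
    n1 <- dedupeSequences(same)
    expect_equal(nrow(n1), 1L)
    expect_equal(n1$id, "r1")
    expect_equal(n1$multiplicity, 3L)
    expect_equal(n1$sources, "r1,r2,r3")

    distinct <- c(a = "MKWLF", b = "MKWLA", c = "MKWAA")
    n2 <- dedupeSequences(distinct)
    expect_equal(nrow(n2), 3L)
    expect_equal(n2$multiplicity, c(1L, 1L, 1L))

    expect_equal(nrow(dedupeSequences(setNames(character(), character()))), 0L)
})

test_that("single nodes give edgeless graphs; identical pairs connect at 100", {
    g1 <- buildSSN(dedupeSequences(c(a = "MKWLFGWWLFMKWLFGWWLF")))
    expect_equal(nrow(ssnEdges(g1)), 0L)
    g2 <- buildSSN(dedupeSequences(c(a = "MKWLFGWWLFMKWLFGWWLF",
                                     b = "MKWLFGWWLFMKWLFGWWLW")))
    expect_equal(nrow(ssnEdges(g2)), 1L)
    expect_gte(ssnEdges(g2)$identity_pct, 90)
})

test_that("a mutant family connects at 50% and disconnects at 90%", {
    set.seed(501)
    anc <- randProtein(80)
    fam <- vapply(1:4, function(i)
        as.character(suppressWarnings(mutateToIdentity(anc, 78))),
        character(1))
    names(fam) <- paste0("m", 1:4)
    # verify by direct pairwise measurement (brute-force pair check)
    pid <- combn(4, 2, function(ij)
        alignLocal(fam[[ij[1]]], fam[[ij[2]]])$identity_pct)
    expect_true(all(pid > 50) && all(pid < 90))
    nodes <- dedupeSequences(fam)
    g50 <- assignGroups(buildSSN(nodes, identity_threshold_pct = 50))
    expect_equal(unique(g50$group_id), 1L)
    g90 <- assignGroups(buildSSN(nodes, identity_threshold_pct = 90))
    expect_true(all(g90$is_singleton))
})

test_that("group assignment matches a union-find oracle on random graphs", {
    set.seed(502)
    for (trial in 1:200) {
        n <- sample(2:12, 1)
        ids <- sprintf("n%02d", seq_len(n))
        nEdges <- sample(0:(n * 2), 1)
        edges <- if (nEdges > 0) data.frame(
            node_a = sample(ids, nEdges, TRUE),
            node_b = sample(ids, nEdges, TRUE),
            stringsAsFactors = FALSE) else
            data.frame(node_a = character(), node_b = character())
        edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
        graph <- fakeGraph(ids, edges)
        got <- assignGroups(graph)
        want <- ufComponents(ids, ssnEdges(graph))
        # identical partitions: compare canonical forms (sorted member sets)
        oracleParts <- sort(vapply(want, function(x)
            paste(sort(x), collapse = ","), character(1)))
        gotOf <- ifelse(got$is_singleton, -seq_len(n), got$group_id)
        gotParts <- sort(vapply(split(got$id, gotOf), function(x)
            paste(sort(x), collapse = ","), character(1)))
        expect_equal(unname(gotParts), unname(oracleParts), info = trial)
        # ranking: group 1 is (one of) the largest
        if (any(!got$is_singleton)) {
            sizes <- table(got$group_id)
            expect_equal(unname(sizes[["1"]]), max(sizes))
        }
    }
})

test_that("raising the identity threshold only refines the partition", {
    set.seed(503)
    anc <- randProtein(70)
    seqs <- c(vapply(c(95, 90, 85, 75, 65), function(t)
        as.character(suppressWarnings(mutateToIdentity(anc, t))),
        character(1)), randProtein(70))
    names(seqs) <- paste0("s", seq_along(seqs))
    nodes <- dedupeSequences(seqs)
    for (pair in list(c(40, 60), c(50, 70), c(60, 80))) {
        lo <- assignGroups(buildSSN(nodes, identity_threshold_pct = pair[1]))
        hi <- assignGroups(buildSSN(nodes, identity_threshold_pct = pair[2]))
        # nodes together at the higher threshold are together at the lower
        for (g in unique(na.omit(hi$group_id))) {
            ids <- hi$id[!is.na(hi$group_id) & hi$group_id == g]
            loGroups <- lo$group_id[match(ids, lo$id)]
            expect_equal(length(unique(loGroups)), 1L)
            expect_false(anyNA(loGroups))
        }
    }
})

test_that("group sizes and singletons partition the node set", {
    set.seed(504)
    seqs <- setNames(vapply(rep(60, 8), randProtein, character(1)),
                     paste0("p", 1:8))
    nodes <- dedupeSequences(seqs)
    grp <- assignGroups(buildSSN(nodes))
    expect_equal(sum(grp$group_size[!duplicated(grp$group_id) &
                                        !is.na(grp$group_id)]) +
                     sum(grp$is_singleton),
                 nrow(nodes))
})

test_that("the six subgroup ii bacteriocins co-cluster at the default cutoff", {
    seeds <- defaultSeedSet()
    info <- as.data.frame(seedInfo(seeds))
    prec <- info[info$role == "precursor", ]
    seqs <- setNames(as.character(seedSequences(seeds))[prec$id], prec$id)
    nodes <- dedupeSequences(seqs)
    grp <- assignGroups(buildSSN(nodes))
    sg2 <- paste0("prec_", c("acidocin_B", "gassericin_A",
                             "butyrovibriocin_AR10", "plantaricyclin_A",
                             "plantacyclin_B21AG", "paracyclicin"))
    g <- grp$group_id[match(sg2, grp$id)]
    expect_false(anyNA(g))
    expect_equal(length(unique(g)), 1L)
    # and no subgroup i precursor joins that component
    others <- grp$id[!is.na(grp$group_id) & grp$group_id == g[1]]
    expect_setequal(others, sg2)
})
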
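# Independent oracles and small fixture builders used across the suite.

aa20 <- c("A","R","N","D","C","Q","E","G","H","I","L",
          "M","F","P","S","T","W","Y","V","K")

randProtein <- function(len) paste(sample(aa20, len, TRUE), collapse = "")

# --- brute-force alignment oracle (full enumeration, no DP) -----------------

# global affine alignment score of two short strings by enumerating every
# monotone alignment path; gap of length L costs open + (L-1)*extend
bruteGlobalAffine <- function(a, b, mat, open = 11, extend = 1) {
    ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
    n <- length(ra); m <- length(rb)
    rec <- function(i, j, last) {
        if (i > n && j > m) return(0)
        best <- -Inf
        if (i <= n && j <= m)
            best <- max(best, mat[ra[i], rb[j]] + rec(i + 1, j + 1, "M"))
        if (i <= n)
            best <- max(best, -(if (last == "U") extend else open) +
                            rec(i + 1, j, "U"))
        if (j <= m)
            best <- max(best, -(if (last == "L") extend else open) +
                            rec(i, j + 1, "L"))
        best
    }
    rec(1, 1, "M")
}

# optimal local score = best global score over all substring pairs (empty
# alignment scores 0)
bruteLocalAffine <- function(a, b, mat, open = 11, extend = 1) {
    na <- nchar(a); nb <- nchar(b)
    best <- 0
    for (i1 in seq_len(na)) for (i2 in i1:na)
        for (j1 in seq_len(nb)) for (j2 in j1:nb) {
            s <- bruteGlobalAffine(substr(a, i1, i2), substr(b, j1, j2),
                                   mat, open, extend)
            if (s > best) best <- s
        }
    best
}

# --- isoelectric point grid oracle ------------------------------------------

# vectorized charge curve from residue counts (independent of netCharge)
chargeCurve <- function(sequence, pH, mode = "linear", pka = pkaTable()) {
    r <- strsplit(sequence, "")[[1]]
    cnt <- table(factor(r, levels = LETTERS))
    pos <- cnt[["R"]] / (1 + 10^(pH - pka[["R"]])) +
        cnt[["K"]] / (1 + 10^(pH - pka[["K"]])) +
        cnt[["H"]] / (1 + 10^(pH - pka[["H"]]))
    neg <- cnt[["D"]] / (1 + 10^(pka[["D"]] - pH)) +
        cnt[["E"]] / (1 + 10^(pka[["E"]] - pH)) +
        cnt[["C"]] / (1 + 10^(pka[["C"]] - pH)) +
        cnt[["Y"]] / (1 + 10^(pka[["Y"]] - pH))
    if (mode == "linear") {
        pos <- pos + 1 / (1 + 10^(pH - pka[["nterm"]]))
        neg <- neg + 1 / (1 + 10^(pka[["cterm"]] - pH))
    }
    pos - neg
}

# two-stage grid scan at 1e-5 resolution (coarse bracket, fine scan)
gridPI <- function(sequence, mode = "linear", pka = pkaTable()) {
    coarse <- seq(0.001, 13.999, by = 0.01)
    z <- chargeCurve(sequence, coarse, mode, pka)
    if (all(z > 0) || all(z < 0) || all(z == 0)) return(NA_real_)
    k <- which(diff(sign(z)) != 0)[1]
    if (is.na(k)) return(NA_real_)
    fine <- seq(max(0.001, coarse[k] - 0.02),
                min(13.999, coarse[k + 1] + 0.02), by = 1e-5)
    zf <- chargeCurve(sequence, fine, mode, pka)
    fine[which.min(abs(zf))]
}

# --- union-find partition oracle --------------------------------------------

ufComponents <- function(ids, edges) {
    parent <- seq_along(ids)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (nrow(edges)) for (k in seq_len(nrow(edges))) {
        ra <- find(match(edges$node_a[k], ids))
        rb <- find(match(edges$node_b[k], ids))
        if (ra != rb) parent[rb] <- ra
    }
    roots <- vapply(seq_along(ids), find, integer(1))
    split(ids, roots)
}

# an SSNGraph with prescribed edges (identities set above any threshold)
fakeGraph <- function(ids, edges) {
    nodes <- data.frame(id = ids, sequence = ids, multiplicity = 1L,
                        sources = ids, stringsAsFactors = FALSE)
    edf <- if (nrow(edges)) data.frame(
        node_a = pmin(edges$node_a, edges$node_b),
        node_b = pmax(edges$node_a, edges$node_b),
        identity_pct = 100, score = 100, stringsAsFactors = FALSE)
    else data.frame(node_a = character(), node_b = character(),
                    identity_pct = numeric(), score = numeric(),
                    stringsAsFactors = FALSE)
    edf <- edf[!duplicated(paste(edf$node_a, edf$node_b)) &
                   edf$node_a != edf$node_b, , drop = FALSE]
    methods::new("SSNGraph", nodes = nodes, edges = edf,
                 params = list(identity_threshold_pct = 0, min_score = 0))
}

# --- window fixture ---------------------------------------------------------

mkWindow <- function(dna, genes = NULL, genome_id = "w", contig_id = "c1",
                     span_start = 1L) {
    if (is.null(genes))
        genes <- data.frame(id = character(), start = integer(),
                            end = integer(), strand = character(),
                            feature_kind = character(), product = character(),
                            protein = character(), premature_stop = logical(),
                            stringsAsFactors = FALSE)
    structure(list(genome_id = genome_id, contig_id = contig_id,
                   anchor_id = if (nrow(genes)) genes$id[1] else "anchor",
                   genes = genes,
                   span = c(span_start, span_start + nchar(dna) - 1L),
                   dna = dna),
              class = "cm_cluster_window")
}
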
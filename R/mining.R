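## Cluster mining: transporter-anchored neighborhood extraction, role
## annotation against the seed set, and the co-occurrence filter (precursor +
## SpoIIM + transporter => pass).

#' Extract the genome neighborhood around an anchor gene
#'
#' Up to `k` genes on each side of the anchor on the same contig, truncated
#' at contig ends. The window span covers every selected gene and the DNA
#' slice matches the span exactly.
#'
#' @param genome a [GenomeRecord-class].
#' @param anchor_id `protein_id` of the anchor feature (the transporter hit).
#' @param k genes kept on each side (default 10, common genome-neighborhood
#'   practice for RiPP clusters).
#' @return a list of class `cm_cluster_window`: `genome_id`, `contig_id`,
#'   `anchor_id`, `genes` (data.frame: id, start, end, strand, feature_kind,
#'   product, protein, premature_stop), `span`, `dna`.
#' @export
extractWindow <- function(genome, anchor_id, k = 10L) {
    stopifnot(methods::is(genome, "GenomeRecord"), k >= 1L)
    ft <- genome@features
    md <- S4Vectors::mcols(ft)
    hit <- which(md$protein_id == anchor_id)
    if (!length(hit)) stop("anchor not found in genome: ", anchor_id)
    hit <- hit[1L]
    ctg <- as.character(GenomicRanges::seqnames(ft))[hit]
    onCtg <- which(as.character(GenomicRanges::seqnames(ft)) == ctg)
    pos <- match(hit, onCtg)
    sel <- onCtg[max(1L, pos - k):min(length(onCtg), pos + k)]
    genes <- data.frame(
        id = as.character(md$protein_id[sel]),
        start = GenomicRanges::start(ft)[sel],
        end = GenomicRanges::end(ft)[sel],
        strand = as.character(GenomicRanges::strand(ft))[sel],
        feature_kind = as.character(md$feature_kind[sel]),
        product = as.character(md$product[sel]),
        protein = as.character(md$protein[sel]),
        premature_stop = md$premature_stop[sel],
        stringsAsFactors = FALSE)
    span <- c(min(genes$start), max(genes$end))
    dna <- substr(as.character(genome@contigs[[ctg]]), span[1], span[2])
    structure(list(genome_id = genome@genomeId, contig_id = ctg,
                   anchor_id = anchor_id, genes = genes,
                   span = as.integer(span), dna = dna),
              class = "cm_cluster_window")
}

# best passing hit per (window protein, role); also unthresholded best
# precursor identity for reporting
.roleHits <- function(targets, seeds, params, thresholds) {
    info <- as.data.frame(seedInfo(seeds))
    seqs <- as.character(seedSequences(seeds))
    hits <- searchProteome(stats::setNames(seqs, info$id), targets, params,
                           thresholds)
    if (nrow(hits))
        hits$role <- info$role[match(hits$query_id, info$id)]
    hits
}

#' Annotate roles in a window and apply the co-occurrence filter
#'
#' Every window protein (annotated CDS translation or scanned ORF) is
#' searched against the seed entries; a gene receives the role of its best
#' passing hit (one role per gene; ties resolved by the priority precursor >
#' spoIIM > transporter, precursors being the scarce signal). Precursor
#' candidacy additionally requires the length bounds and either seed identity
#' at or above `precursor_min_identity` (`support = "homology"`) or the
#' physicochemical heuristic (GRAVY >= -0.5 and length within bounds;
#' `support = "heuristic"`, reported for bioprospecting but too permissive to
#' drive the verdict -- roughly half of all random small ORFs satisfy it).
#' The verdict is `pass` iff the window holds a homology-supported precursor
#' candidate, a SpoIIM homolog and a transporter.
#' Accessory families (Yip1, peptidase by homology; transposase by product
#' annotation text) are reported as flags only.
#'
#' @param window from [extractWindow()].
#' @param seeds a [SeedSet-class].
#' @param params [alignParams()].
#' @param thresholds [searchThresholds()].
#' @param min_prec_aa,max_prec_aa precursor length bounds (default 25-150).
#' @param precursor_min_identity identity floor for homology-based precursor
#'   candidacy; defaults to the search identity threshold.
#' @param suppress_shadow passed to [scanOrfs()].
#' @return a [CandidateBGC-class].
#' @export
classifyRoles <- function(window, seeds, params = alignParams(),
                          thresholds = searchThresholds(),
                          min_prec_aa = 25L, max_prec_aa = 150L,
                          precursor_min_identity =
                              thresholds$min_identity_pct,
                          suppress_shadow = TRUE) {
    stopifnot(inherits(window, "cm_cluster_window"),
              methods::is(seeds, "SeedSet"))
    info <- as.data.frame(seedInfo(seeds))
    if (!any(info$role == "precursor"))
        stop("seed set has no precursor entries")

    genes <- window$genes
    usable <- genes$feature_kind == "CDS" & !genes$premature_stop &
        !is.na(genes$protein) & nzchar(genes$protein)
    prots <- stats::setNames(genes$protein[usable], genes$id[usable])
    orfs <- scanOrfs(window, min_prec_aa, max_prec_aa,
                     suppress_shadow = suppress_shadow)
    targets <- c(prots,
                 if (nrow(orfs)) stats::setNames(orfs$sequence, orfs$id))
    rolePriority <- c(precursor = 1, spoIIM = 2, transporter = 3, yip1 = 4,
                      peptidase = 5, immunity = 6)

    geneRole <- stats::setNames(rep(NA_character_, length(targets)),
                                names(targets))
    geneScore <- stats::setNames(rep(NA_real_, length(targets)),
                                 names(targets))
    geneIdent <- stats::setNames(rep(NA_real_, length(targets)),
                                 names(targets))
    if (length(targets)) {
        hits <- .roleHits(targets, seeds, params, thresholds)
        if (nrow(hits)) {
            hits <- hits[order(hits$target_id, -hits$score,
                               rolePriority[hits$role]), , drop = FALSE]
            best <- hits[!duplicated(hits$target_id), , drop = FALSE]
            geneRole[best$target_id] <- best$role
            geneScore[best$target_id] <- best$score
            geneIdent[best$target_id] <- best$identity_pct
        }
    }

    # precursor candidates: annotated or scanned, inside the length bounds,
    # homologous to a seed precursor or plausibly precursor-like
    precSeeds <- as.character(seedSequences(seeds, "precursor"))
    candIds <- names(targets)[nchar(targets) >= min_prec_aa &
                                  nchar(targets) <= max_prec_aa]
    precRows <- list()
    for (id in candIds) {
        if (!is.na(geneRole[[id]]) && geneRole[[id]] != "precursor") next
        seqc <- targets[[id]]
        bestIdent <- 0
        for (ps in precSeeds) {
            al <- alignLocal(ps, seqc, params)
            if (al$score >= thresholds$min_raw_score / 2 &&
                al$identity_pct > bestIdent &&
                al$query_coverage >= thresholds$min_query_coverage)
                bestIdent <- al$identity_pct
        }
        g <- tryCatch(gravy(seqc), error = function(e) NA_real_)
        byHomology <- (identical(geneRole[[id]], "precursor") &&
                           geneIdent[[id]] >= precursor_min_identity) ||
            bestIdent >= precursor_min_identity
        byHeuristic <- !is.na(g) && g >= -0.5
        if (!byHomology && !byHeuristic) next
        support <- if (byHomology) "homology" else "heuristic"
        if (id %in% names(prots)) {
            gi <- match(id, genes$id)
            precRows[[length(precRows) + 1L]] <- data.frame(
                id = id, sequence = seqc, length = nchar(seqc),
                start = genes$start[gi], end = genes$end[gi],
                strand = genes$strand[gi], origin = "annotated_cds",
                seed_identity_pct = max(bestIdent,
                    if (identical(geneRole[[id]], "precursor"))
                        geneIdent[[id]] else 0),
                support = support,
                stringsAsFactors = FALSE)
        } else {
            oi <- match(id, orfs$id)
            precRows[[length(precRows) + 1L]] <- data.frame(
                id = id, sequence = seqc, length = nchar(seqc),
                start = orfs$start[oi], end = orfs$end[oi],
                strand = orfs$strand[oi], origin = "orf_scan",
                seed_identity_pct = max(bestIdent,
                    if (identical(geneRole[[id]], "precursor"))
                        geneIdent[[id]] else 0),
                support = support,
                stringsAsFactors = FALSE)
        }
    }
    precursorsDf <- if (length(precRows)) do.call(rbind, precRows) else
        data.frame(id = character(), sequence = character(),
                   length = integer(), start = integer(), end = integer(),
                   strand = character(), origin = character(),
                   seed_identity_pct = numeric(), support = character(),
                   stringsAsFactors = FALSE)
    if (nrow(precursorsDf)) {
        precursorsDf$gravy <- vapply(precursorsDf$sequence, function(s)
            tryCatch(gravy(s), error = function(e) NA_real_), numeric(1))
        precursorsDf$net_charge <- vapply(precursorsDf$sequence, function(s)
            netCharge(s, 7, "cyclic"), numeric(1))
        precursorsDf$subgroup <- vapply(precursorsDf$sequence,
                                        classifySubgroup, character(1))
        rownames(precursorsDf) <- NULL
    } else {
        precursorsDf$gravy <- numeric(0)
        precursorsDf$net_charge <- numeric(0)
        precursorsDf$subgroup <- character(0)
    }

    genesOut <- genes[, c("id", "start", "end", "strand", "product")]
    genesOut$role <- geneRole[genesOut$id]
    genesOut$role_score <- geneScore[genesOut$id]
    genesOut$role_identity <- geneIdent[genesOut$id]
    # precursor ORFs recovered outside the annotation also count as genes
    precOrf <- precursorsDf[precursorsDf$origin == "orf_scan" &
                                precursorsDf$support == "homology", ,
                            drop = FALSE]
    if (nrow(precOrf)) {
        genesOut <- rbind(genesOut, data.frame(
            id = precOrf$id, start = precOrf$start, end = precOrf$end,
            strand = precOrf$strand, product = "putative precursor (ORF scan)",
            role = "precursor", role_score = NA_real_,
            role_identity = precOrf$seed_identity_pct,
            stringsAsFactors = FALSE))
        genesOut <- genesOut[order(genesOut$start), , drop = FALSE]
        rownames(genesOut) <- NULL
    }
    homologyIds <- precursorsDf$id[precursorsDf$support == "homology"]
    genesOut$role[genesOut$id %in% homologyIds] <- "precursor"

    hasPrec <- length(homologyIds) > 0L
    hasSpo <- any(genesOut$role == "spoIIM", na.rm = TRUE)
    hasTra <- any(genesOut$role == "transporter", na.rm = TRUE)
    fails <- c(if (!hasPrec) "no_precursor",
               if (!hasSpo) "no_spoiim",
               if (!hasTra) "no_transporter")
    prodTxt <- tolower(ifelse(is.na(genes$product), "", genes$product))
    flags <- c(yip1 = any(genesOut$role == "yip1", na.rm = TRUE),
               transposase = any(grepl("transposase", prodTxt, fixed = TRUE)),
               peptidase = any(genesOut$role == "peptidase", na.rm = TRUE))
    methods::new("CandidateBGC",
                 genomeId = window$genome_id, contigId = window$contig_id,
                 anchorId = window$anchor_id, span = window$span,
                 genes = genesOut, precursors = precursorsDf, flags = flags,
                 verdict = if (length(fails)) "fail" else "pass",
                 failReasons = as.character(fails))
}

#' Mine one genome for head-to-tail cyclized bacteriocin clusters
#'
#' Runs the transporter-guided search: seed transporters against the genome
#' proteome, one window per (merged) anchor neighborhood, role annotation and
#' the co-occurrence filter per window. Anchors closer than `k` genes on the
#' same contig collapse into a single window around the best-scoring hit.
#'
#' @inheritParams classifyRoles
#' @param genome a [GenomeRecord-class].
#' @param k window half-width in genes.
#' @return list: `bgcs` (list of [CandidateBGC-class]), `transporter_hits`
#'   (data.frame), `n_windows`.
#' @export
mineGenome <- function(genome, seeds = defaultSeedSet(),
                       params = alignParams(),
                       thresholds = searchThresholds(), k = 10L,
                       min_prec_aa = 25L, max_prec_aa = 150L,
                       suppress_shadow = TRUE) {
    proteome <- genomeProteome(genome)
    empty <- list(bgcs = list(),
                  transporter_hits = searchProteome(character(0) |>
                      stats::setNames(character(0)), proteome),
                  n_windows = 0L)
    if (!length(proteome)) {
        empty$transporter_hits <- data.frame()
        return(empty)
    }
    info <- as.data.frame(seedInfo(seeds))
    tra <- as.character(seedSequences(seeds, "transporter"))
    names(tra) <- info$id[info$role == "transporter"]
    hits <- searchProteome(tra, proteome, params, thresholds)
    if (!nrow(hits)) return(list(bgcs = list(), transporter_hits = hits,
                                 n_windows = 0L))

    ft <- genome@features
    md <- S4Vectors::mcols(ft)
    anchorIds <- unique(hits$target_id)
    bestScore <- vapply(anchorIds, function(a)
        max(hits$score[hits$target_id == a]), numeric(1))
    idx <- match(anchorIds, md$protein_id)
    ctg <- as.character(GenomicRanges::seqnames(ft))[idx]
    # gene index along its contig, for merging nearby anchors
    geneIndex <- vapply(seq_along(idx), function(i) {
        onCtg <- which(as.character(GenomicRanges::seqnames(ft)) == ctg[i])
        match(idx[i], onCtg)
    }, integer(1))
    ord <- order(ctg, geneIndex)
    anchorIds <- anchorIds[ord]; ctg <- ctg[ord]
    geneIndex <- geneIndex[ord]; bestScore <- bestScore[ord]
    groups <- integer(length(anchorIds))
    gcur <- 0L
    for (i in seq_along(anchorIds)) {
        if (i == 1L || ctg[i] != ctg[i - 1L] ||
            geneIndex[i] - geneIndex[i - 1L] > k)
            gcur <- gcur + 1L
        groups[i] <- gcur
    }
    reps <- vapply(split(seq_along(anchorIds), groups), function(ii)
        ii[which.max(bestScore[ii])], integer(1))
    bgcs <- lapply(anchorIds[reps], function(a) {
        w <- extractWindow(genome, a, k)
        classifyRoles(w, seeds, params, thresholds, min_prec_aa, max_prec_aa,
                      suppress_shadow = suppress_shadow)
    })
    list(bgcs = bgcs, transporter_hits = hits, n_windows = length(bgcs))
}
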
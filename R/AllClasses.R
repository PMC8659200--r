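#' GenomeRecord: an annotated bacterial genome
#'
#' Container for one genome: nucleotide contigs plus CDS features. Coordinates
#' are 1-based inclusive on the forward strand of the named contig (GFF3
#' convention); any half-open arithmetic is internal.
#'
#' Feature metadata columns: `feature_kind` (`"CDS"` or `"other"`),
#' `protein_id`, `product`, `protein` (translation, `NA` when unavailable) and
#' `premature_stop` (logical; CDS with an internal stop codon are kept but
#' flagged and excluded from proteome searches).
#'
#' @slot genomeId single string identifying the genome.
#' @slot contigs [Biostrings::DNAStringSet] of contig sequences (A/C/G/T/N).
#' @slot features [GenomicRanges::GRanges] of gene features, sorted by
#'   (contig, start).
#'
#' @seealso [loadAnnotatedGenome()], [genomeProteome()], [generateGenome()]
#' @export
setClass("GenomeRecord",
         slots = c(genomeId = "character",
                   contigs = "DNAStringSet",
                   features = "GRanges"))

setValidity("GenomeRecord", function(object) {
    msgs <- character()
    if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
        !nzchar(object@genomeId))
        msgs <- c(msgs, "genomeId must be a single non-empty string")
    if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs)))
        msgs <- c(msgs, "contigs must have unique names")
    ft <- object@features
    if (length(ft)) {
        bad <- !(as.character(GenomicRanges::seqnames(ft)) %in%
                     names(object@contigs))
        if (any(bad))
            msgs <- c(msgs, sprintf("feature contig(s) not in FASTA: %s",
                                    paste(unique(as.character(
                                        GenomicRanges::seqnames(ft))[bad]),
                                        collapse = ", ")))
        if (!all(as.character(GenomicRanges::strand(ft)) %in% c("+", "-")))
            msgs <- c(msgs, "feature strand must be '+' or '-'")
        lens <- Biostrings::width(object@contigs)[
            match(as.character(GenomicRanges::seqnames(ft)),
                  names(object@contigs))]
        over <- !is.na(lens) & (GenomicRanges::start(ft) < 1L |
                                    GenomicRanges::end(ft) > lens)
        if (any(over))
            msgs <- c(msgs, "feature coordinates exceed contig bounds")
        o <- order(as.character(GenomicRanges::seqnames(ft)),
                   GenomicRanges::start(ft))
        if (!identical(o, seq_along(ft)))
            msgs <- c(msgs, "features must be sorted by (contig, start)")
    }
    if (length(msgs)) msgs else TRUE
})

#' SeedSet: characterized bacteriocin reference proteins
#'
#' The driver sequences for homology search and role annotation: precursor,
#' transporter and SpoIIM proteins of characterized head-to-tail cyclized
#' bacteriocins, plus optional accessory families (Yip1, peptidase, immunity).
#' Each entry carries the bacteriocin name, its role, and the subgroup label
#' (`"i"` cationic, `"ii"` neutral/hydrophobic, `"unknown"`).
#'
#' A valid seed set contains at least one transporter and one SpoIIM entry.
#'
#' @slot sequences [Biostrings::AAStringSet], names are unique entry ids.
#' @slot info [S4Vectors::DataFrame] with columns `id`, `bacteriocin`, `role`,
#'   `subgroup`, `leader_length` (NA when unknown), aligned with `sequences`.
#' @slot provenance free-text note on where the entries come from.
#'
#' @seealso [readSeedSet()], [defaultSeedSet()]
#' @export
setClass("SeedSet",
         slots = c(sequences = "AAStringSet",
                   info = "DataFrame",
                   provenance = "character"))

SEED_ROLES <- c("precursor", "transporter", "spoIIM", "yip1", "peptidase",
                "immunity")

setValidity("SeedSet", function(object) {
    msgs <- character()
    if (length(object@sequences) != nrow(object@info))
        msgs <- c(msgs, "sequences and info must have equal length")
    need <- c("id", "bacteriocin", "role", "subgroup", "leader_length")
    if (!all(need %in% colnames(object@info)))
        msgs <- c(msgs, paste("info must have columns:",
                              paste(need, collapse = ", ")))
    else {
        if (!all(object@info$role %in% SEED_ROLES))
            msgs <- c(msgs, paste("role must be one of:",
                                  paste(SEED_ROLES, collapse = ", ")))
        if (!all(object@info$subgroup %in% c("i", "ii", "unknown")))
            msgs <- c(msgs, "subgroup must be 'i', 'ii' or 'unknown'")
        if (!any(object@info$role == "transporter"))
            msgs <- c(msgs, "seed set needs at least one transporter entry")
        if (!any(object@info$role == "spoIIM"))
            msgs <- c(msgs, "seed set needs at least one spoIIM entry")
        if (anyDuplicated(object@info$id))
            msgs <- c(msgs, "entry ids must be unique")
        if (!identical(as.character(object@info$id),
                       names(object@sequences)))
            msgs <- c(msgs, "names(sequences) must equal info$id")
    }
    if (length(msgs)) msgs else TRUE
})

#' CandidateBGC: a screened genome neighborhood
#'
#' One transporter-anchored window together with its role annotation and the
#' co-occurrence verdict. The verdict is `"pass"` exactly when the window holds
#' a precursor candidate, a SpoIIM homolog and a transporter; accessory
#' families (Yip1, transposase, peptidase) are reported as flags and never
#' influence the verdict.
#'
#' @slot genomeId,contigId location of the window.
#' @slot anchorId feature id of the transporter hit anchoring the window.
#' @slot span integer length-2 (start, end) of the window on the contig.
#' @slot genes data.frame of window genes: id, start, end, strand, product,
#'   role, role_score, role_identity.
#' @slot precursors data.frame of precursor candidates: id, sequence, length,
#'   start, end, strand, origin (`annotated_cds` / `orf_scan`),
#'   seed_identity_pct, support (`homology` for seed-backed candidates,
#'   `heuristic` for exploratory precursor-like small ORFs; only the former
#'   satisfy the filter), gravy, net_charge, subgroup.
#' @slot flags named logical vector: yip1, transposase, peptidase.
#' @slot verdict `"pass"` or `"fail"`.
#' @slot failReasons character vector drawn from `no_precursor`, `no_spoiim`,
#'   `no_transporter` (empty on pass).
#'
#' @seealso [classifyRoles()], [mineGenome()]
#' @export
setClass("CandidateBGC",
         slots = c(genomeId = "character",
                   contigId = "character",
                   anchorId = "character",
                   span = "integer",
                   genes = "data.frame",
                   precursors = "data.frame",
                   flags = "logical",
                   verdict = "character",
                   failReasons = "character"))

setValidity("CandidateBGC", function(object) {
    msgs <- character()
    if (!object@verdict %in% c("pass", "fail"))
        msgs <- c(msgs, "verdict must be 'pass' or 'fail'")
    hasPrec <- nrow(object@precursors) > 0L &&
        any(object@precursors$support == "homology")
    hasSpo <- any(object@genes$role == "spoIIM", na.rm = TRUE)
    hasTra <- any(object@genes$role == "transporter", na.rm = TRUE)
    expected <- if (hasPrec && hasSpo && hasTra) "pass" else "fail"
    if (!identical(object@verdict, expected))
        msgs <- c(msgs, "verdict inconsistent with role presence")
    if (length(object@span) != 2L || object@span[1] > object@span[2])
        msgs <- c(msgs, "span must be (start, end) with start <= end")
    if (length(msgs)) msgs else TRUE
})

#' SSNGraph: a thresholded sequence similarity network
#'
#' Nodes are unique precursor sequences (exact-string deduplication; the node
#' id is the first-seen record id and the multiplicity counts the source
#' records). Edges connect node pairs whose local alignment reaches both the
#' percent-identity threshold and the raw-score floor.
#'
#' @slot nodes data.frame: id, sequence, multiplicity, sources
#'   (comma-separated record ids).
#' @slot edges data.frame: node_a, node_b, identity_pct, score (undirected,
#'   node_a < node_b lexicographically, unique).
#' @slot params list: identity_threshold_pct, min_score, and the alignment
#'   parameters used.
#'
#' @seealso [dedupeSequences()], [buildSSN()], [assignGroups()]
#' @export
setClass("SSNGraph",
         slots = c(nodes = "data.frame",
                   edges = "data.frame",
                   params = "list"))

setValidity("SSNGraph", function(object) {
    msgs <- character()
    ed <- object@edges
    if (nrow(ed)) {
        if (any(ed$node_a == ed$node_b))
            msgs <- c(msgs, "self-edges are not allowed")
        if (!all(ed$node_a %in% object@nodes$id) ||
            !all(ed$node_b %in% object@nodes$id))
            msgs <- c(msgs, "edge endpoints must be nodes")
        key <- paste(pmin(ed$node_a, ed$node_b), pmax(ed$node_a, ed$node_b))
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate undirected edges")
        thr <- object@params$identity_threshold_pct
        if (!is.null(thr) && any(ed$identity_pct < thr))
            msgs <- c(msgs, "edge below the identity threshold")
    }
    if (anyDuplicated(object@nodes$id))
        msgs <- c(msgs, "node ids must be unique")
    if (length(msgs)) msgs else TRUE
})
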
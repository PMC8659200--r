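## Leader-peptide cleavage-site transfer: map a characterized anchor's
## cleavage position through a group alignment onto every member.

#' Transfer a leader cleavage site from an anchor through an MSA
#'
#' The anchor's cleavage position (residue index of the last leader residue;
#' 0 for leaderless) is mapped to its alignment column; each member's
#' transferred position is the count of its own residues in columns up to
#' that column (members gapped at the anchor column thus inherit the nearest
#' preceding residue). Confidence is the member-vs-anchor percent identity
#' over the columns where at least one of the two has a residue.
#'
#' @param msa a `cm_msa` from [alignMsa()].
#' @param anchor_id id of the characterized anchor sequence in the MSA.
#' @param anchor_site 0 <= site <= anchor length; residue index of the last
#'   leader residue.
#' @return data.frame, one row per MSA member: `id`, `leader_end` (transferred
#'   position), `core_start`, `residue_before_site` (last leader residue,
#'   `NA` when leaderless -- for checks such as the conserved asparaginyl
#'   site), `confidence_identity_pct`.
#' @export
transferCleavage <- function(msa, anchor_id, anchor_site) {
    stopifnot(inherits(msa, "cm_msa"))
    if (!anchor_id %in% names(msa$aligned))
        stop("anchor not in MSA: ", anchor_id)
    anchorLen <- length(msa$column_map[[anchor_id]])
    stopifnot(anchor_site >= 0, anchor_site <= anchorLen)
    cutCol <- if (anchor_site == 0) 0L else
        msa$column_map[[anchor_id]][anchor_site]
    anchorRow <- strsplit(msa$aligned[[anchor_id]], "")[[1]]
    rows <- lapply(names(msa$aligned), function(id) {
        cm <- msa$column_map[[id]]
        site <- sum(cm <= cutCol)
        memberRow <- strsplit(msa$aligned[[id]], "")[[1]]
        informative <- memberRow != "-" | anchorRow != "-"
        ident <- if (any(informative))
            100 * sum(memberRow == anchorRow & memberRow != "-" &
                          informative) / sum(informative) else 0
        seqc <- gsub("-", "", msa$aligned[[id]], fixed = TRUE)
        data.frame(id = id, leader_end = site, core_start = site + 1L,
                   residue_before_site = if (site >= 1L)
                       substr(seqc, site, site) else NA_character_,
                   confidence_identity_pct = ident,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-group cleavage annotation from the curated anchor table
#'
#' For each SSN group containing a characterized seed precursor with a known
#' leader length, aligns the group members and transfers the anchor's
#' cleavage site. Groups without a characterized member get no prediction.
#'
#' @param groupSequences named list: group id -> named character vector of
#'   member sequences.
#' @param anchors data.frame from [cleavageSiteTable()].
#' @param params [alignParams()].
#' @return named list of [transferCleavage()] data.frames (possibly empty).
#' @export
annotateGroupCleavage <- function(groupSequences,
                                  anchors = cleavageSiteTable(),
                                  params = alignParams()) {
    out <- list()
    for (gname in names(groupSequences)) {
        members <- groupSequences[[gname]]
        hit <- anchors$seed_id %in% names(members)
        if (!any(hit) || length(members) < 2L) next
        anchor <- anchors[which(hit)[1L], ]
        msa <- alignMsa(members, params)
        out[[gname]] <- transferCleavage(msa, anchor$seed_id,
                                         anchor$leader_length)
    }
    out
}
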
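## Deterministic TSV exports: SSN edge/node tables for network viewers and
## the per-hit / per-group result tables.

#' Write an SSN as edge-list + node-attribute TSVs
#'
#' `<prefix>_edges.tsv`: node_a, node_b, percent_identity, alignment_score.
#' `<prefix>_nodes.tsv`: id, multiplicity, group_id, subgroup, gravy, pI
#' (cyclic; empty when undefined). Both load directly into standard network
#' viewers.
#'
#' @param graph an [SSNGraph-class].
#' @param prefix output path prefix.
#' @param groups optional [assignGroups()] result.
#' @param profiles optional [physchemProfile()] result for the node
#'   sequences.
#' @return invisibly, the two paths.
#' @export
writeEdgeList <- function(graph, prefix, groups = NULL, profiles = NULL) {
    stopifnot(methods::is(graph, "SSNGraph"))
    edges <- graph@edges
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    colnames(edges) <- c("node_a", "node_b", "percent_identity",
                         "alignment_score")
    edgePath <- paste0(prefix, "_edges.tsv")
    nodePath <- paste0(prefix, "_nodes.tsv")
    utils::write.table(edges, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nodes <- graph@nodes[order(graph@nodes$id), , drop = FALSE]
    attr <- data.frame(id = nodes$id, multiplicity = nodes$multiplicity,
                       stringsAsFactors = FALSE)
    attr$group_id <- if (!is.null(groups))
        groups$group_id[match(attr$id, groups$id)] else NA_integer_
    if (!is.null(profiles)) {
        m <- match(attr$id, profiles$id)
        attr$subgroup <- profiles$subgroup[m]
        attr$gravy <- profiles$gravy[m]
        attr$pI <- profiles$pI_cyclic[m]
    } else {
        attr$subgroup <- NA_character_
        attr$gravy <- NA_real_
        attr$pI <- NA_real_
    }
    utils::write.table(attr, nodePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(edgePath, nodePath))
}

#' Read back an SSN edge list
#'
#' Inverse of the edge table written by [writeEdgeList()]; used for
#' round-trip checks and to feed external layouts back in.
#'
#' @param edge_path the `_edges.tsv` file.
#' @return data.frame: node_a, node_b, identity_pct, score.
#' @export
readEdgeList <- function(edge_path) {
    df <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "numeric", "numeric"))
    colnames(df) <- c("node_a", "node_b", "identity_pct", "score")
    df
}

#' Write the per-hit and per-group result tables
#'
#' `<out_dir>/hits.tsv`: one row per passing precursor candidate (genome,
#' contig, coordinates, roles found in the window, precursor sequence, node
#' id, group, subgroup). `<out_dir>/groups.tsv`: one row per numbered group
#' (group_id, n_unique, n_genomes) plus a singleton summary row. Output is
#' sorted and regeneration from the same inputs is byte-identical.
#'
#' @param bgcs list of [CandidateBGC-class] (pass verdicts are reported).
#' @param nodes [dedupeSequences()] result used for the SSN.
#' @param groups [assignGroups()] result.
#' @param profiles [physchemProfile()] result for the nodes.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the two paths.
#' @export
writeResultsTables <- function(bgcs, nodes, groups, profiles, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!all(nodes$id %in% groups$id))
        stop("validation error: node(s) without group assignment: ",
             paste(setdiff(nodes$id, groups$id), collapse = ", "))
    if (!all(nodes$id %in% profiles$id))
        stop("validation error: node(s) without physchem profile: ",
             paste(setdiff(nodes$id, profiles$id), collapse = ", "))
    hitRows <- list()
    for (bgc in bgcs) {
        if (verdict(bgc) != "pass") next
        prec <- precursors(bgc)
        roles <- sort(unique(stats::na.omit(windowGenes(bgc)$role)))
        for (i in seq_len(nrow(prec))) {
            nodeIdx <- which(nodes$sequence == prec$sequence[i])
            nodeId <- if (length(nodeIdx)) nodes$id[nodeIdx[1L]] else NA
            hitRows[[length(hitRows) + 1L]] <- data.frame(
                genome = bgc@genomeId, contig = bgc@contigId,
                start = prec$start[i], end = prec$end[i],
                strand = prec$strand[i],
                roles_found = paste(roles, collapse = ","),
                precursor = prec$sequence[i],
                node_id = nodeId,
                group_id = groups$group_id[match(nodeId, groups$id)],
                subgroup = profiles$subgroup[match(nodeId, profiles$id)],
                stringsAsFactors = FALSE)
        }
    }
    hits <- if (length(hitRows)) do.call(rbind, hitRows) else
        data.frame(genome = character(), contig = character(),
                   start = integer(), end = integer(), strand = character(),
                   roles_found = character(), precursor = character(),
                   node_id = character(), group_id = integer(),
                   subgroup = character(), stringsAsFactors = FALSE)
    hits <- hits[order(hits$genome, hits$contig, hits$start), , drop = FALSE]

    grpRows <- list()
    for (g in sort(unique(stats::na.omit(groups$group_id)))) {
        ids <- groups$id[!is.na(groups$group_id) & groups$group_id == g]
        nGen <- length(unique(hits$genome[hits$node_id %in% ids]))
        grpRows[[length(grpRows) + 1L]] <- data.frame(
            group_id = as.character(g), n_unique = length(ids),
            n_genomes = nGen, stringsAsFactors = FALSE)
    }
    singles <- groups$id[groups$is_singleton]
    grpRows[[length(grpRows) + 1L]] <- data.frame(
        group_id = "singletons", n_unique = length(singles),
        n_genomes = length(unique(hits$genome[hits$node_id %in% singles])),
        stringsAsFactors = FALSE)
    grp <- do.call(rbind, grpRows)

    hitPath <- file.path(out_dir, "hits.tsv")
    grpPath <- file.path(out_dir, "groups.tsv")
    utils::write.table(hits, hitPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(grp, grpPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(hitPath, grpPath))
}
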
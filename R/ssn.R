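## Sequence similarity network: exact-string deduplication, thresholded
## all-by-all local alignment, size-ranked connected components.

#' Deduplicate precursor records into SSN nodes
#'
#' Exact-string deduplication: one node per distinct sequence, multiplicity =
#' number of source records, node id = first-seen record id.
#'
#' @param records named character vector or [Biostrings::AAStringSet].
#' @return data.frame: `id`, `sequence`, `multiplicity`, `sources`
#'   (comma-separated record ids, first-seen order).
#' @export
dedupeSequences <- function(records) {
    records <- .asNamedProteins(records, "records")
    if (!length(records))
        return(data.frame(id = character(), sequence = character(),
                          multiplicity = integer(), sources = character(),
                          stringsAsFactors = FALSE))
    first <- !duplicated(unname(records))
    uniq <- records[first]
    sources <- vapply(unname(uniq), function(s)
        paste(names(records)[unname(records) == s], collapse = ","),
        character(1))
    data.frame(id = names(uniq), sequence = unname(uniq),
               multiplicity = as.integer(table(unname(records))[unname(uniq)]),
               sources = sources, stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the thresholded sequence similarity network
#'
#' Computes the local alignment of every unordered node pair and adds an edge
#' when the percent identity reaches `identity_threshold_pct` and the raw
#' score reaches `min_score`. The raw-score floor replaces the E-value
#' pre-filter of database search tools, which has no meaning without a
#' database context.
#'
#' @param nodes data.frame from [dedupeSequences()] (or any data.frame with
#'   `id` and `sequence`).
#' @param params [alignParams()].
#' @param identity_threshold_pct percent identity cutoff (default 50, the
#'   cutoff at which characterized circular-bacteriocin precursors partition
#'   into coherent groups).
#' @param min_score raw-score floor (default 60, the raw-score analog of an
#'   E-value near 1e-5 for peptide-length sequences under this scoring
#'   scheme).
#' @return an [SSNGraph-class].
#' @export
buildSSN <- function(nodes, params = alignParams(),
                     identity_threshold_pct = 50, min_score = 60) {
    stopifnot(is.data.frame(nodes), nrow(nodes) >= 1L,
              all(c("id", "sequence") %in% colnames(nodes)))
    if (!"multiplicity" %in% colnames(nodes))
        nodes$multiplicity <- 1L
    if (!"sources" %in% colnames(nodes))
        nodes$sources <- nodes$id
    n <- nrow(nodes)
    rows <- list()
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                al <- alignLocal(nodes$sequence[i], nodes$sequence[j], params)
                if (al$identity_pct >= identity_threshold_pct &&
                    al$score >= min_score) {
                    a <- nodes$id[i]; b <- nodes$id[j]
                    rows[[length(rows) + 1L]] <- data.frame(
                        node_a = min(a, b), node_b = max(a, b),
                        identity_pct = al$identity_pct, score = al$score,
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    edges <- if (length(rows)) do.call(rbind, rows) else
        data.frame(node_a = character(), node_b = character(),
                   identity_pct = numeric(), score = numeric(),
                   stringsAsFactors = FALSE)
    methods::new("SSNGraph", nodes = nodes, edges = edges,
                 params = list(identity_threshold_pct = identity_threshold_pct,
                               min_score = min_score,
                               matrix_name = params$matrix_name,
                               gap_open = params$gap_open,
                               gap_extend = params$gap_extend))
}

#' Assign size-ranked groups from an SSN
#'
#' Connected components of the thresholded graph. Components with at least
#' two members are numbered 1..n by descending unique-member count (ties
#' broken lexicographically by smallest member id); single-node components
#' are singletons (`group_id = NA`).
#'
#' @param graph an [SSNGraph-class].
#' @return data.frame with one row per node: `id`, `group_id` (NA for
#'   singletons), `group_size`, `is_singleton`.
#' @export
assignGroups <- function(graph) {
    stopifnot(methods::is(graph, "SSNGraph"))
    nodes <- graph@nodes
    g <- igraph::graph_from_data_frame(
        graph@edges[, c("node_a", "node_b"), drop = FALSE],
        directed = FALSE, vertices = nodes$id)
    comp <- igraph::components(g)
    membership <- comp$membership[nodes$id]
    sizes <- as.integer(table(membership)[as.character(membership)])
    compIds <- unique(membership[sizes >= 2L])
    if (length(compIds)) {
        compSize <- vapply(compIds, function(cc) sum(membership == cc),
                           integer(1))
        minMember <- vapply(compIds, function(cc)
            min(nodes$id[membership == cc]), character(1))
        o <- order(-compSize, minMember)
        rank <- stats::setNames(seq_along(compIds), compIds[o])
    } else rank <- integer(0)
    groupId <- rep(NA_integer_, nrow(nodes))
    big <- sizes >= 2L
    groupId[big] <- rank[as.character(membership[big])]
    data.frame(id = nodes$id, group_id = groupId, group_size = sizes,
               is_singleton = !big, stringsAsFactors = FALSE,
               row.names = NULL)
}
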
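## Distance-based phylogeny of precursor peptides: global-alignment identity
## distances, neighbor-joining (Saitou-Nei) via ape, Newick + annotation
## export. Replaces maximum-likelihood inference: the tree's role here is
## visual grouping of the network groups, which distance NJ serves.

#' Pairwise alignment distance matrix
#'
#' `d(i, j) = 1 - n_identical / n_aligned_columns` from the global alignment
#' of each pair (end gaps charged, same scoring as the rest of the package).
#'
#' @param sequences named character vector or [Biostrings::AAStringSet]
#'   (unique ids).
#' @param params [alignParams()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distanceMatrix <- function(sequences, params = alignParams()) {
    sequences <- .asNamedProteins(sequences, "sequences")
    if (anyDuplicated(names(sequences))) stop("duplicate sequence ids")
    n <- length(sequences)
    D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        al <- alignGlobal(sequences[[i]], sequences[[j]], params)
        d <- 1 - al$n_identical / max(1L, al$n_aligned_columns)
        D[i, j] <- d; D[j, i] <- d
    }
    D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]). Negative branch-length
#' estimates, an artifact NJ can produce on noisy distances, are clamped to
#' zero and flagged. With exactly two taxa a trivial two-leaf tree is
#' returned by convention and flagged.
#'
#' @param D symmetric distance matrix with >= 2 taxa.
#' @param annotations optional data.frame with column `id` plus any leaf
#'   metadata (group, subgroup, GRAVY, ...), attached for export.
#' @return list of class `cm_phylo`: `tree` ([ape::phylo], unrooted),
#'   `clamped_branches` (integer count), `two_taxon` (logical),
#'   `annotations`.
#' @export
njTree <- function(D, annotations = NULL) {
    stopifnot(is.matrix(D), nrow(D) == ncol(D))
    if (nrow(D) < 2L) stop("njTree needs at least 2 taxa")
    if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
    if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
    twoTaxon <- nrow(D) == 2L
    if (twoTaxon) {
        tree <- ape::read.tree(text = sprintf(
            "(%s:%.10g,%s:%.10g);", rownames(D)[1], D[1, 2] / 2,
            rownames(D)[2], D[1, 2] / 2))
    } else {
        tree <- ape::nj(stats::as.dist(D))
    }
    clamped <- sum(tree$edge.length < 0)
    tree$edge.length[tree$edge.length < 0] <- 0
    structure(list(tree = tree, clamped_branches = as.integer(clamped),
                   two_taxon = twoTaxon, annotations = annotations),
              class = "cm_phylo")
}

#' Write a tree as Newick plus a leaf-annotation table
#'
#' The annotation TSV (id + metadata columns) is a flat table importable by
#' standard tree viewers.
#'
#' @param phylo from [njTree()].
#' @param newick_path output Newick path.
#' @param annotations_path optional TSV path.
#' @return invisibly, the paths written.
#' @export
writeTree <- function(phylo, newick_path, annotations_path = NULL) {
    stopifnot(inherits(phylo, "cm_phylo"))
    ape::write.tree(phylo$tree, file = newick_path, digits = 12)
    if (!is.null(annotations_path) && !is.null(phylo$annotations))
        utils::write.table(phylo$annotations, annotations_path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(c(newick_path, annotations_path))
}
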
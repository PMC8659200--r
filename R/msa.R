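## Native progressive multiple alignment: UPGMA guide tree on pairwise
## global-alignment identity distances, then profile-profile alignment with
## the same substitution matrix and affine gap model as the pairwise search.

# frequency profile (21 x ncol) of a character matrix of aligned rows;
# gaps contribute zero weight so a gap column scores 0 against anything
.profileOf <- function(alnMat) {
    nc <- ncol(alnMat)
    prof <- matrix(0, 21L, nc, dimnames = list(AA_ALPHABET21, NULL))
    for (j in seq_len(nc)) {
        col <- alnMat[, j]
        col <- col[col != "-"]
        if (length(col)) {
            tab <- table(factor(col, levels = AA_ALPHABET21))
            prof[, j] <- as.numeric(tab) / nrow(alnMat)
        }
    }
    prof
}

.mergeAlignments <- function(mA, mB, params) {
    pA <- .profileOf(mA); pB <- .profileOf(mB)
    S <- t(pA) %*% params$matrix %*% pB
    res <- .alignProfileCpp(S, params$gap_open, params$gap_extend)
    path <- res$path
    out <- matrix("-", nrow(mA) + nrow(mB), length(path))
    ia <- 0L; ib <- 0L
    for (k in seq_along(path)) {
        if (path[k] != 3L) { ia <- ia + 1L; out[seq_len(nrow(mA)), k] <- mA[, ia] }
        if (path[k] != 2L) { ib <- ib + 1L;
            out[nrow(mA) + seq_len(nrow(mB)), k] <- mB[, ib] }
    }
    rownames(out) <- c(rownames(mA), rownames(mB))
    out
}

#' Progressive multiple sequence alignment
#'
#' Guide tree: UPGMA (average-linkage clustering) on pairwise
#' global-alignment identity distances (`1 - identical/columns`). Profiles
#' are then aligned progressively along the merge order with sum-of-pairs
#' column scoring under the same substitution matrix and affine gap penalties
#' as [alignLocal()]. Deterministic for a given input.
#'
#' @param sequences named character vector or [Biostrings::AAStringSet]
#'   (>= 2 sequences, unique ids).
#' @param params [alignParams()].
#' @return list of class `cm_msa`: `aligned` (named character vector of
#'   equal-length gapped rows, input order), `n_columns`, `column_map` (list:
#'   per sequence, residue index -> column index).
#' @export
alignMsa <- function(sequences, params = alignParams()) {
    sequences <- .asNamedProteins(sequences, "sequences")
    if (length(sequences) < 2L)
        stop("alignMsa needs at least 2 sequences")
    if (anyDuplicated(names(sequences))) stop("duplicate sequence ids")
    n <- length(sequences)
    D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        al <- alignGlobal(sequences[[i]], sequences[[j]], params)
        d <- 1 - al$n_identical / max(1L, al$n_aligned_columns)
        D[i, j] <- d; D[j, i] <- d
    }
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    mats <- lapply(sequences, function(s)
        matrix(strsplit(s, "")[[1]], nrow = 1L))
    for (i in seq_along(mats)) rownames(mats[[i]]) <- names(sequences)[i]
    merged <- vector("list", nrow(hc$merge))
    getm <- function(k) if (k < 0) mats[[-k]] else merged[[k]]
    for (step in seq_len(nrow(hc$merge))) {
        a <- getm(hc$merge[step, 1]); b <- getm(hc$merge[step, 2])
        merged[[step]] <- .mergeAlignments(a, b, params)
    }
    finalMat <- if (nrow(hc$merge)) merged[[nrow(hc$merge)]] else mats[[1]]
    finalMat <- finalMat[names(sequences), , drop = FALSE]
    aligned <- apply(finalMat, 1L, paste, collapse = "")
    columnMap <- lapply(names(sequences), function(id) {
        which(finalMat[id, ] != "-")
    })
    names(columnMap) <- names(sequences)
    structure(list(aligned = aligned, n_columns = ncol(finalMat),
                   column_map = columnMap),
              class = "cm_msa")
}

#' Write an MSA as aligned FASTA
#'
#' @param msa from [alignMsa()].
#' @param path output path.
#' @export
writeMsa <- function(msa, path) {
    stopifnot(inherits(msa, "cm_msa"))
    con <- file(path, "w")
    on.exit(close(con))
    for (id in names(msa$aligned))
        writeLines(c(paste0(">", id), msa$aligned[[id]]), con)
    invisible(path)
}
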
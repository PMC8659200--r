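## Sequence-logo matrices: per-column residue frequencies and information
## content in bits, computed from a multiple alignment. Rendering is left to
## plotting layers; the matrix is the contract.

#' Sequence-logo matrix of an alignment
#'
#' Per column: residue frequencies over the 20 canonical letters (gap- and
#' X-excluded), the gap fraction, and the information content
#' `IC = log2(20) - H` where `H` is the Shannon entropy (bits) of the residue
#' frequencies. No small-sample correction is applied. All-gap columns have
#' undefined frequencies (all zero), gap fraction 1, and IC 0 by convention.
#'
#' @param msa a `cm_msa` from [alignMsa()], or a named character vector of
#'   equal-length gapped sequences.
#' @return list of class `cm_logo`: `frequencies` (20 x n_columns matrix),
#'   `gap_fraction`, `information_bits` (numeric vectors per column),
#'   `n_sequences`.
#' @examples
#' m <- alignMsa(c(a = "MKW", b = "MKW"))
#' logoMatrix(m)$information_bits  # log2(20) at every column
#' @export
logoMatrix <- function(msa) {
    rows <- if (inherits(msa, "cm_msa")) msa$aligned else msa
    stopifnot(length(rows) >= 1L,
              length(unique(nchar(rows))) == 1L)
    mat <- do.call(rbind, strsplit(unname(rows), ""))
    nc <- ncol(mat)
    canon <- AA_ALPHABET21[1:20]
    freqs <- matrix(0, 20L, nc, dimnames = list(canon, NULL))
    gapFrac <- numeric(nc)
    ic <- numeric(nc)
    for (j in seq_len(nc)) {
        col <- mat[, j]
        gapFrac[j] <- mean(col == "-")
        res <- col[col %in% canon]
        if (!length(res)) { ic[j] <- 0; next }
        f <- as.numeric(table(factor(res, levels = canon))) / length(res)
        freqs[, j] <- f
        nz <- f[f > 0]
        ic[j] <- log2(20) + sum(nz * log2(nz))
    }
    structure(list(frequencies = freqs, gap_fraction = gapFrac,
                   information_bits = ic, n_sequences = length(rows)),
              class = "cm_logo")
}

#' Write a logo matrix as TSV
#'
#' One row per alignment column: position, gap fraction, information content
#' and the 20 residue frequencies.
#'
#' @param logo from [logoMatrix()].
#' @param path output path.
#' @export
writeLogoMatrix <- function(logo, path) {
    stopifnot(inherits(logo, "cm_logo"))
    df <- data.frame(position = seq_along(logo$information_bits),
                     gap_fraction = logo$gap_fraction,
                     information_bits = logo$information_bits,
                     t(logo$frequencies), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
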
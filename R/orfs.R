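## Six-frame small-ORF scanning inside cluster windows. Precursor genes are
## often left unannotated by genome pipelines; this recovers them.

.START_CODONS <- c("ATG", "GTG", "TTG")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs on one strand of a window DNA string. Returns rows with 1-based
# coordinates on the *given* string; caller maps to contig coordinates.
.scanStrand <- function(dna, min_len, max_len) {
    n <- nchar(dna)
    out <- list()
    for (off in 0:2) {
        ncod <- (n - off) %/% 3L
        if (ncod < min_len + 1L) next
        starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
        codons <- substring(dna, starts, starts + 2L)
        isStop <- codons %in% .STOP_CODONS
        isStart <- codons %in% .START_CODONS
        prevStop <- 0L
        for (ci in seq_len(ncod)) {
            if (!isStop[ci]) next
            # candidate starts after the previous stop; longest qualifying kept
            cand <- which(isStart[seq_len(ci - 1L)])
            cand <- cand[cand > prevStop]
            if (length(cand)) {
                lens <- ci - cand  # translated length in codons (stop excl.)
                ok <- lens >= min_len & lens <= max_len
                if (any(ok)) {
                    s <- cand[which(ok)[1L]]  # earliest start = longest ORF
                    out[[length(out) + 1L]] <- c(startPos = starts[s],
                                                 endPos = starts[ci] + 2L)
                }
            }
            prevStop <- ci
        }
    }
    if (!length(out))
        return(data.frame(startPos = integer(), endPos = integer()))
    as.data.frame(do.call(rbind, out))
}

#' Scan a cluster window for small open reading frames
#'
#' All six reading frames of the window DNA are scanned for ORFs beginning at
#' ATG/GTG/TTG and ending at the first in-frame stop, keeping translated
#' lengths (stop excluded) within the given bounds. Per stop position and
#' frame only the longest qualifying ORF is kept. ORFs wholly contained in an
#' annotated CDS on the same strand are suppressed, as are (by default)
#' shadow ORFs whose span overlaps annotated CDS on either strand over more
#' than half their length -- the reverse-strand interior of a real gene is
#' not a credible peptide gene.
#'
#' @param window a window from [extractWindow()].
#' @param min_len_aa,max_len_aa translated-length bounds (default 25-150 aa,
#'   the size range of characterized precursors).
#' @param suppress_shadow drop ORFs overlapping annotated CDS (either strand)
#'   over more than 50% of their length.
#' @return data.frame: `id`, `sequence`, `length`, `start`, `end` (contig
#'   coordinates, 1-based inclusive, stop codon included), `strand`,
#'   `origin = "orf_scan"`.
#' @export
scanOrfs <- function(window, min_len_aa = 25L, max_len_aa = 150L,
                     suppress_shadow = TRUE) {
    stopifnot(min_len_aa >= 1L, min_len_aa < max_len_aa)
    dna <- window$dna
    n <- nchar(dna)
    fwd <- .scanStrand(dna, min_len_aa, max_len_aa)
    rev <- .scanStrand(.revcomp(dna), min_len_aa, max_len_aa)
    rows <- list()
    addOrf <- function(startPos, endPos, strand) {
        if (strand == "+") {
            s <- window$span[1] + startPos - 1L
            e <- window$span[1] + endPos - 1L
            cds <- substr(dna, startPos, endPos)
        } else {
            s <- window$span[1] + (n - endPos + 1L) - 1L
            e <- window$span[1] + (n - startPos + 1L) - 1L
            cds <- substr(.revcomp(dna), startPos, endPos)
        }
        tr <- .translateCDS(cds)
        rows[[length(rows) + 1L]] <<- data.frame(
            sequence = tr$protein, length = nchar(tr$protein),
            start = s, end = e, strand = strand,
            origin = "orf_scan", stringsAsFactors = FALSE)
    }
    if (nrow(fwd)) for (i in seq_len(nrow(fwd)))
        addOrf(fwd$startPos[i], fwd$endPos[i], "+")
    if (nrow(rev)) for (i in seq_len(nrow(rev)))
        addOrf(rev$startPos[i], rev$endPos[i], "-")
    if (!length(rows))
        return(data.frame(id = character(), sequence = character(),
                          length = integer(), start = integer(),
                          end = integer(), strand = character(),
                          origin = character(), stringsAsFactors = FALSE))
    orfs <- do.call(rbind, rows)

    genes <- window$genes
    cds <- genes[genes$feature_kind == "CDS", , drop = FALSE]
    if (nrow(cds) && nrow(orfs)) {
        drop <- logical(nrow(orfs))
        for (i in seq_len(nrow(orfs))) {
            os <- orfs$start[i]; oe <- orfs$end[i]
            within <- cds$start <= os & cds$end >= oe &
                cds$strand == orfs$strand[i]
            if (any(within)) { drop[i] <- TRUE; next }
            if (suppress_shadow) {
                ov <- pmax(0L, pmin(oe, cds$end) - pmax(os, cds$start) + 1L)
                if (any(ov > (oe - os + 1L) / 2)) drop[i] <- TRUE
            }
        }
        orfs <- orfs[!drop, , drop = FALSE]
    }
    if (nrow(orfs)) {
        o <- order(orfs$start, orfs$end, orfs$strand)
        orfs <- orfs[o, , drop = FALSE]
        orfs <- cbind(id = sprintf("%s_orf%02d", window$contig_id,
                                   seq_len(nrow(orfs))),
                      orfs, stringsAsFactors = FALSE)
        rownames(orfs) <- NULL
    } else {
        orfs <- cbind(id = character(), orfs)
    }
    orfs
}
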
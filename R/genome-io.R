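## Genome input/output: FASTA contigs + GFF3 CDS features, translation under
## the bacterial genetic code (transl_table 11).

.geneticCode11 <- function() {
    if (is.null(.cm_cache$gc11))
        .cm_cache$gc11 <- Biostrings::getGeneticCode("11")
    .cm_cache$gc11
}

# Translate one CDS nucleotide string (already on the coding strand) under
# the bacterial code. Vectorized codon lookup: much faster than S4 dispatch
# in the ORF-scanning hot path. Codons containing N translate to X; the
# initiator codon (ATG/GTG/TTG/...) translates to M; the trailing stop is
# trimmed; internal stops set the premature flag.
.translateCDS <- function(dna) {
    n <- nchar(dna)
    if (n < 3L) return(list(protein = NA_character_, premature_stop = FALSE))
    n <- n - n %% 3L
    gc <- .geneticCode11()
    starts <- seq.int(1L, n, 3L)
    codons <- substring(dna, starts, starts + 2L)
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"  # ambiguous nucleotide(s)
    if (codons[1L] %in% attr(gc, "alt_init_codons") || codons[1L] == "ATG")
        aa[1L] <- "M"
    prem <- FALSE
    if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    if (any(aa == "*")) prem <- TRUE
    list(protein = paste(aa, collapse = ""), premature_stop = prem)
}

.revcomp <- function(dna) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", dna), "",
                       fixed = TRUE)[[1]]), collapse = "")
}

#' Load an annotated genome from FASTA (+ optional GFF3)
#'
#' Reads nucleotide contigs and, when a GFF3 is supplied, its CDS features.
#' Coordinates stay 1-based inclusive. CDS without a supplied translation are
#' translated under the bacterial code (table 11) honoring strand; CDS with an
#' internal stop codon are kept but flagged `premature_stop` and later
#' excluded from proteome searches.
#'
#' @param fasta_path nucleotide FASTA of contigs.
#' @param gff3_path optional GFF3; its seqnames must all occur in the FASTA.
#' @param genome_id genome identifier; defaults to the FASTA basename.
#' @return a [GenomeRecord-class].
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">c1", "ATGAAATAA"), fa)
#' g <- loadAnnotatedGenome(fa)
#' length(features(g))  # 0
#' @export
loadAnnotatedGenome <- function(fasta_path, gff3_path = NULL,
                                genome_id = NULL) {
    if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
    contigs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                        error = function(e)
                            stop("malformed FASTA '", fasta_path, "': ",
                                 conditionMessage(e), call. = FALSE))
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    if (is.null(genome_id))
        genome_id <- sub("\\.[^.]*$", "", basename(fasta_path))
    feats <- GenomicRanges::GRanges()
    if (!is.null(gff3_path)) {
        if (!file.exists(gff3_path)) stop("GFF3 not found: ", gff3_path)
        gff <- tryCatch(rtracklayer::import(gff3_path, format = "gff3"),
                        error = function(e)
                            stop("malformed GFF3 '", gff3_path, "': ",
                                 conditionMessage(e), call. = FALSE))
        bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gff))),
                       names(contigs))
        if (length(bad))
            stop("GFF3 references contig(s) absent from FASTA: ",
                 paste(bad, collapse = ", "))
        feats <- .buildFeatures(gff, contigs)
    }
    methods::new("GenomeRecord", genomeId = genome_id, contigs = contigs,
                 features = feats)
}

.buildFeatures <- function(gff, contigs) {
    md <- S4Vectors::mcols(gff)
    kind <- if ("type" %in% colnames(md)) as.character(md$type) else
        rep("other", length(gff))
    keep <- kind %in% c("CDS", "gene", "mRNA") | TRUE
    gr <- gff[keep]
    md <- S4Vectors::mcols(gr)
    featKind <- ifelse(as.character(md$type) == "CDS", "CDS", "other")
    getcol <- function(nm) {
        if (nm %in% colnames(md)) {
            v <- md[[nm]]
            if (is.list(v))
                v <- vapply(v, function(x)
                    if (length(x)) as.character(x[[1]]) else NA_character_,
                    character(1))
            as.character(v)
        } else rep(NA_character_, length(gr))
    }
    pid <- getcol("protein_id")
    idcol <- getcol("ID")
    pid <- ifelse(is.na(pid), idcol, pid)
    pid <- ifelse(is.na(pid),
                  sprintf("feat%04d", seq_along(gr)), pid)
    product <- getcol("product")
    strnd <- as.character(GenomicRanges::strand(gr))
    strnd[strnd == "*"] <- "+"
    out <- GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(gr)),
        ranges = IRanges::IRanges(GenomicRanges::start(gr),
                                  GenomicRanges::end(gr)),
        strand = strnd)
    protein <- rep(NA_character_, length(out))
    prem <- rep(FALSE, length(out))
    for (i in seq_along(out)) {
        if (featKind[i] != "CDS") next
        ctg <- as.character(GenomicRanges::seqnames(out))[i]
        dna <- substr(as.character(contigs[[ctg]]),
                      GenomicRanges::start(out)[i],
                      GenomicRanges::end(out)[i])
        if (strnd[i] == "-") dna <- .revcomp(dna)
        tr <- .translateCDS(dna)
        protein[i] <- tr$protein
        prem[i] <- tr$premature_stop
    }
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        feature_kind = featKind, protein_id = pid, product = product,
        protein = protein, premature_stop = prem)
    o <- order(as.character(GenomicRanges::seqnames(out)),
               GenomicRanges::start(out))
    out[o]
}

#' Extract the searchable proteome of a genome
#'
#' Translations of all CDS features, excluding those flagged with a premature
#' internal stop. Names are the feature protein ids.
#'
#' @param genome a [GenomeRecord-class].
#' @return named character vector of protein sequences (possibly empty).
#' @export
genomeProteome <- function(genome) {
    stopifnot(methods::is(genome, "GenomeRecord"))
    ft <- genome@features
    if (!length(ft)) return(stats::setNames(character(), character()))
    md <- S4Vectors::mcols(ft)
    keep <- md$feature_kind == "CDS" & !md$premature_stop &
        !is.na(md$protein) & nzchar(md$protein)
    stats::setNames(as.character(md$protein[keep]),
                    as.character(md$protein_id[keep]))
}

#' Write a genome back to FASTA + GFF3
#'
#' Inverse of [loadAnnotatedGenome()]: contigs to nucleotide FASTA, features
#' to GFF3 with `protein_id` and `product` attributes. Round-tripping
#' preserves contig sequences and feature coordinates exactly.
#'
#' @param genome a [GenomeRecord-class].
#' @param fasta_path,gff3_path output paths (GFF3 skipped when `NULL`).
#' @return invisibly, the paths written.
#' @export
writeGenome <- function(genome, fasta_path, gff3_path = NULL) {
    stopifnot(methods::is(genome, "GenomeRecord"))
    Biostrings::writeXStringSet(genome@contigs, fasta_path)
    if (!is.null(gff3_path)) {
        ft <- genome@features
        lines <- c("##gff-version 3")
        if (length(ft)) {
            md <- S4Vectors::mcols(ft)
            attrs <- sprintf("ID=%s;product=%s",
                             md$protein_id,
                             ifelse(is.na(md$product), "hypothetical protein",
                                    md$product))
            lines <- c(lines, sprintf(
                "%s\tcycloMiner\t%s\t%d\t%d\t.\t%s\t0\t%s",
                as.character(GenomicRanges::seqnames(ft)),
                ifelse(md$feature_kind == "CDS", "CDS", "region"),
                GenomicRanges::start(ft), GenomicRanges::end(ft),
                as.character(GenomicRanges::strand(ft)), attrs))
        }
        writeLines(lines, gff3_path)
    }
    invisible(c(fasta_path, gff3_path))
}
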
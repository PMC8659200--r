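## Seed set handling: the characterized-bacteriocin reference entries that
## drive the homology search, role annotation and subgroup fixtures.

#' Construct a SeedSet
#'
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   protein sequences; names are unique entry ids.
#' @param info data.frame with columns `id`, `bacteriocin`, `role`,
#'   `subgroup`, and optionally `leader_length`; one row per sequence.
#' @param provenance free-text provenance note.
#' @return a [SeedSet-class].
#' @export
SeedSet <- function(sequences, info, provenance = "user-supplied") {
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(sequences)
    info <- as.data.frame(info)
    if (!"leader_length" %in% colnames(info))
        info$leader_length <- NA_integer_
    info <- S4Vectors::DataFrame(
        id = as.character(info$id),
        bacteriocin = as.character(info$bacteriocin),
        role = as.character(info$role),
        subgroup = as.character(info$subgroup),
        leader_length = as.integer(info$leader_length))
    sequences <- sequences[match(info$id, names(sequences))]
    methods::new("SeedSet", sequences = sequences, info = info,
                 provenance = provenance)
}

#' Read a seed set from FASTA + roles TSV
#'
#' The TSV must have columns `id`, `bacteriocin`, `role` (one of precursor,
#' transporter, spoIIM, yip1, peptidase, immunity), `subgroup` (i, ii,
#' unknown) and optionally `leader_length`; every id must have a sequence in
#' the FASTA.
#'
#' @param fasta_path protein FASTA.
#' @param roles_path tab-separated role annotation.
#' @param provenance provenance note; defaults to the file paths.
#' @return a [SeedSet-class].
#' @export
readSeedSet <- function(fasta_path, roles_path, provenance = NULL) {
    seqs <- Biostrings::readAAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    info <- utils::read.delim(roles_path, stringsAsFactors = FALSE)
    missing <- setdiff(info$id, names(seqs))
    if (length(missing))
        stop("seed id(s) without FASTA sequence: ",
             paste(missing, collapse = ", "))
    if (is.null(provenance))
        provenance <- paste0(basename(fasta_path), " + ",
                             basename(roles_path))
    SeedSet(as.character(seqs), info, provenance)
}

#' The bundled default seed set (synthetic stand-in)
#'
#' Entries for the 19 characterized head-to-tail cyclized bacteriocins
#' (13 subgroup i, 6 subgroup ii), each with a precursor, a transporter and a
#' SpoIIM protein, plus accessory Yip1 and peptidase families. The sequences
#' are *synthetic stand-ins*: constructed to carry the documented properties
#' of the real proteins (family structure, cationic vs neutral/hydrophobic
#' cores, leader lengths within 2-48 aa, asparaginyl cleavage sites for the
#' subgroup ii family), not database copies. Replace via [readSeedSet()] for
#' production mining.
#'
#' @return a [SeedSet-class].
#' @export
defaultSeedSet <- function() {
    if (!is.null(.cm_cache$default_seeds)) return(.cm_cache$default_seeds)
    fa <- system.file("extdata", "seeds_synthetic.faa",
                      package = "cycloMiner", mustWork = TRUE)
    tsv <- system.file("extdata", "seed_roles_synthetic.tsv",
                       package = "cycloMiner", mustWork = TRUE)
    out <- readSeedSet(fa, tsv,
                       provenance = "bundled synthetic stand-in seed set")
    .cm_cache$default_seeds <- out
    out
}

#' Curated leader-peptide cleavage sites for characterized anchors
#'
#' One row per characterized bacteriocin with an experimentally supported
#' leader length (the cleavage site is the bond after the last leader
#' residue; 0 means leaderless). For the bundled synthetic seed set these are
#' the designed leader lengths. User-editable: supply any TSV with columns
#' `bacteriocin`, `seed_id`, `leader_length`.
#'
#' @param path optional TSV path; default = bundled table.
#' @return data.frame with columns `bacteriocin`, `seed_id`, `leader_length`.
#' @export
cleavageSiteTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "cleavage_sites_synthetic.tsv",
                            package = "cycloMiner", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
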
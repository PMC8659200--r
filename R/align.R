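## Pairwise local/global protein alignment (Gotoh affine gaps) -- the package's
## search primitive, mirroring protein-BLAST defaults (BLOSUM62, gap open 11,
## extend 1). The dynamic program lives in src/align.cpp.

#' Alignment parameters
#'
#' BLAST-style defaults: BLOSUM62, gap open 11, gap extend 1. A gap of length
#' L costs `gap_open + (L - 1) * gap_extend`. The `X` row and column of the
#' matrix are set to zero so ambiguous residues neither reward nor punish.
#'
#' @param substitution_matrix matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM30"`, `"PAM70"`, `"PAM250"`) or a numeric matrix whose
#'   dimnames cover the 21-letter alphabet.
#' @param gap_open non-negative gap opening cost.
#' @param gap_extend non-negative gap extension cost; must not exceed
#'   `gap_open`.
#' @return a list of class `cm_align_params`.
#' @examples
#' p <- alignParams()
#' p$gap_open
#' @export
alignParams <- function(substitution_matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
    stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
    mat <- .resolveMatrix(substitution_matrix)
    structure(list(matrix_name = if (is.character(substitution_matrix))
                       substitution_matrix else "custom",
                   matrix = mat, gap_open = gap_open,
                   gap_extend = gap_extend),
              class = "cm_align_params")
}

.resolveMatrix <- function(m) {
    if (is.matrix(m)) return(.conformMatrix(m))
    stopifnot(is.character(m), length(m) == 1L)
    key <- paste0("submat_", m)
    if (!is.null(.cm_cache[[key]])) return(.cm_cache[[key]])
    env <- new.env()
    ok <- tryCatch({
        utils::data(list = m, package = "Biostrings", envir = env)
        TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || is.null(env[[m]]))
        stop("unknown substitution matrix: ", m)
    out <- .conformMatrix(env[[m]])
    .cm_cache[[key]] <- out
    out
}

# restrict to the 21-letter alphabet and zero out X (design decision:
# ambiguity is scoreless); strict mode requires the 20 canonical residues
.conformMatrix <- function(mat, strict = TRUE) {
    miss <- setdiff(AA_ALPHABET21, rownames(mat))
    if (strict && length(setdiff(miss, "X")))
        stop("substitution matrix must cover the 20 canonical residues",
             if (length(miss)) paste0(" (missing: ",
                                      paste(miss, collapse = ","), ")"))
    full <- matrix(0, 21L, 21L, dimnames = list(AA_ALPHABET21, AA_ALPHABET21))
    keep <- setdiff(AA_ALPHABET21, miss)
    full[keep, keep] <- mat[keep, keep]
    full["X", ] <- 0
    full[, "X"] <- 0
    storage.mode(full) <- "double"
    full
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix files distributed with BLAST
#' (`#`-comment lines, a header row of residue letters, one labelled row per
#' residue). Letters outside the 21-letter alphabet (B, Z, *, ...) are
#' dropped; a missing `X` is added with all-zero scores.
#'
#' @param path file path.
#' @return numeric 21 x 21 matrix over [AA_ALPHABET21].
#' @export
readSubstitutionMatrix <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (!length(lines)) stop("empty substitution matrix file: ", path)
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
    labels <- vapply(rows, `[`, character(1), 1L)
    vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                     numeric(length(header))))
    dimnames(vals) <- list(labels, header)
    .conformMatrix(vals, strict = FALSE)
}

.encodeAA <- function(seq) {
    x <- match(strsplit(seq, "")[[1]], AA_ALPHABET21)
    if (anyNA(x))
        stop("invalid residue(s) in sequence: ",
             paste(unique(setdiff(strsplit(seq, "")[[1]], AA_ALPHABET21)),
                   collapse = ","))
    x
}

.checkProtein <- function(seq, what = "sequence") {
    if (!is.character(seq) || length(seq) != 1L || is.na(seq))
        stop(what, " must be a single string")
    if (!nzchar(seq)) stop(what, " must be non-empty")
    if (grepl("\\s", seq)) stop(what, " contains whitespace")
    invisible(seq)
}

.alignCore <- function(a, b, params, mode) {
    .checkProtein(a, "sequence a"); .checkProtein(b, "sequence b")
    ea <- .encodeAA(a); eb <- .encodeAA(b)
    res <- .alignPairCpp(ea, eb, params$matrix, params$gap_open,
                         params$gap_extend, mode)
    aAln <- res$a_aln; bAln <- res$b_aln
    nCols <- length(aAln)
    nIdent <- sum(aAln > 0L & aAln == bAln)
    identity <- if (nCols > 0L) 100 * nIdent / nCols else 0
    lut <- c("-", AA_ALPHABET21)
    chA <- if (nCols) paste(lut[aAln + 1L], collapse = "") else ""
    chB <- if (nCols) paste(lut[bAln + 1L], collapse = "") else ""
    nA <- sum(aAln > 0L); nB <- sum(bAln > 0L)
    list(score = res$score,
         identity_pct = identity,
         n_identical = nIdent,
         n_aligned_columns = nCols,
         query_coverage = nA / nchar(a),
         subject_coverage = nB / nchar(b),
         query_start = res$a_start, query_end = res$a_end,
         subject_start = res$b_start, subject_end = res$b_end,
         aligned_query = chA, aligned_subject = chB)
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' Maximal-scoring local alignment under an affine gap model (opening charged
#' at the first gapped position, extension at each additional one). Percent
#' identity is computed BLAST-style over all aligned columns, gap columns
#' included in the denominator. When every pair score is non-positive the
#' optimal local alignment is empty: score 0, zero columns, `NA` intervals.
#'
#' Tie-breaking is deterministic (traceback prefers diagonal, then up, then
#' left; among equal end cells the smallest query, then subject, position).
#'
#' @param a,b protein sequences (strings over the 21-letter alphabet).
#' @param params an [alignParams()] object.
#' @return a list: `score`, `identity_pct`, `n_identical`,
#'   `n_aligned_columns`, `query_coverage`, `subject_coverage`, 1-based
#'   aligned intervals on both sequences, and the gapped aligned strings.
#' @examples
#' alignLocal("MKWVFF", "MKWVFF")$identity_pct  # 100
#' @export
alignLocal <- function(a, b, params = alignParams()) {
    .alignCore(a, b, params, mode = 0L)
}

#' Global (Needleman-Wunsch) protein alignment, end gaps charged
#'
#' Same scoring model as [alignLocal()] but over the full length of both
#' sequences. Used for divergence measurement ([distanceMatrix()],
#' [mutateToIdentity()] verification).
#'
#' @inheritParams alignLocal
#' @return as [alignLocal()]; coverage is 1 for both sequences.
#' @export
alignGlobal <- function(a, b, params = alignParams()) {
    .alignCore(a, b, params, mode = 1L)
}

#' Homology-search thresholds
#'
#' The local-search analog of a web BLAST run: explicit identity, coverage and
#' raw-score cutoffs instead of E-values (deterministic and independent of
#' database size).
#'
#' @param min_identity_pct minimum percent identity over aligned columns.
#' @param min_query_coverage minimum fraction of the query inside the local
#'   alignment.
#' @param min_raw_score minimum raw alignment score.
#' @return a list of class `cm_search_thresholds`.
#' @export
searchThresholds <- function(min_identity_pct = 30, min_query_coverage = 0.5,
                             min_raw_score = 50) {
    stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
              min_query_coverage >= 0, min_query_coverage <= 1,
              min_raw_score >= 0)
    structure(list(min_identity_pct = min_identity_pct,
                   min_query_coverage = min_query_coverage,
                   min_raw_score = min_raw_score),
              class = "cm_search_thresholds")
}

#' Search a proteome with driver sequences
#'
#' Aligns every query against every target and keeps hits passing all
#' thresholds; one best hit (highest score) is retained per (query, target)
#' pair. This is the local stand-in for seeding a database search with
#' characterized transporter sequences.
#'
#' @param queries,proteome named character vectors or
#'   [Biostrings::AAStringSet]; ids must be unique within each collection.
#' @param params [alignParams()].
#' @param thresholds [searchThresholds()].
#' @return data.frame with one row per passing hit: `query_id`, `target_id`,
#'   `score`, `identity_pct`, `query_coverage`, `target_coverage`, aligned
#'   intervals; sorted by (target_id, descending score, query_id).
#' @export
searchProteome <- function(queries, proteome, params = alignParams(),
                           thresholds = searchThresholds()) {
    queries <- .asNamedProteins(queries, "queries")
    proteome <- .asNamedProteins(proteome, "proteome")
    if (anyDuplicated(names(queries)))
        stop("duplicate query ids")
    if (anyDuplicated(names(proteome)))
        stop("duplicate proteome ids")
    rows <- vector("list", length(queries) * length(proteome))
    k <- 0L
    for (qi in seq_along(queries)) {
        for (ti in seq_along(proteome)) {
            al <- alignLocal(queries[[qi]], proteome[[ti]], params)
            if (al$score >= thresholds$min_raw_score &&
                al$identity_pct >= thresholds$min_identity_pct &&
                al$query_coverage >= thresholds$min_query_coverage) {
                k <- k + 1L
                rows[[k]] <- data.frame(
                    query_id = names(queries)[qi],
                    target_id = names(proteome)[ti],
                    score = al$score,
                    identity_pct = al$identity_pct,
                    n_identical = al$n_identical,
                    n_aligned_columns = al$n_aligned_columns,
                    query_coverage = al$query_coverage,
                    target_coverage = al$subject_coverage,
                    query_start = al$query_start, query_end = al$query_end,
                    target_start = al$subject_start,
                    target_end = al$subject_end,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (k == 0L)
        return(data.frame(query_id = character(), target_id = character(),
                          score = numeric(), identity_pct = numeric(),
                          n_identical = integer(),
                          n_aligned_columns = integer(),
                          query_coverage = numeric(),
                          target_coverage = numeric(),
                          query_start = integer(), query_end = integer(),
                          target_start = integer(), target_end = integer(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows[seq_len(k)])
    out[order(out$target_id, -out$score, out$query_id), , drop = FALSE]
}

.asNamedProteins <- function(x, what) {
    if (methods::is(x, "AAStringSet")) x <- as.character(x)
    if (!is.character(x) || is.null(names(x)) || !all(nzchar(names(x))))
        stop(what, " must be a named character vector or AAStringSet")
    x
}
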
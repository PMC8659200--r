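#' @rdname GenomeRecord-class
#' @param object,x a `GenomeRecord`
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname SeedSet-class
#' @export
setGeneric("seedInfo", function(x) standardGeneric("seedInfo"))
#' @rdname SeedSet-class
#' @export
setGeneric("seedSequences", function(x, role = NULL)
    standardGeneric("seedSequences"))
#' @rdname CandidateBGC-class
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname CandidateBGC-class
#' @export
setGeneric("failReasons", function(x) standardGeneric("failReasons"))
#' @rdname CandidateBGC-class
#' @export
setGeneric("precursors", function(x) standardGeneric("precursors"))
#' @rdname CandidateBGC-class
#' @export
setGeneric("windowGenes", function(x) standardGeneric("windowGenes"))
#' @rdname SSNGraph-class
#' @export
setGeneric("ssnNodes", function(x) standardGeneric("ssnNodes"))
#' @rdname SSNGraph-class
#' @export
setGeneric("ssnEdges", function(x) standardGeneric("ssnEdges"))

#' @rdname GenomeRecord-class
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@genomeId)
#' @rdname GenomeRecord-class
#' @export
setMethod("contigs", "GenomeRecord", function(x) x@contigs)
#' @rdname GenomeRecord-class
#' @export
setMethod("features", "GenomeRecord", function(x) x@features)

#' @rdname SeedSet-class
#' @export
setMethod("seedInfo", "SeedSet", function(x) x@info)

#' @describeIn SeedSet-class sequences, optionally restricted to one role.
#' @param role optional role name to subset by.
#' @export
setMethod("seedSequences", "SeedSet", function(x, role = NULL) {
    if (is.null(role)) return(x@sequences)
    stopifnot(role %in% SEED_ROLES)
    x@sequences[x@info$role == role]
})

#' @rdname CandidateBGC-class
#' @export
setMethod("verdict", "CandidateBGC", function(x) x@verdict)
#' @rdname CandidateBGC-class
#' @export
setMethod("failReasons", "CandidateBGC", function(x) x@failReasons)
#' @rdname CandidateBGC-class
#' @export
setMethod("precursors", "CandidateBGC", function(x) x@precursors)
#' @rdname CandidateBGC-class
#' @export
setMethod("windowGenes", "CandidateBGC", function(x) x@genes)

#' @rdname SSNGraph-class
#' @export
setMethod("ssnNodes", "SSNGraph", function(x) x@nodes)
#' @rdname SSNGraph-class
#' @export
setMethod("ssnEdges", "SSNGraph", function(x) x@edges)

setMethod("show", "GenomeRecord", function(object) {
    cat("GenomeRecord:", object@genomeId, "\n")
    cat(" ", length(object@contigs), "contig(s),",
        sum(Biostrings::width(object@contigs)), "bp;",
        length(object@features), "feature(s)\n")
})

setMethod("show", "SeedSet", function(object) {
    cat("SeedSet with", length(object@sequences), "entries\n")
    print(table(role = object@info$role))
    cat(" provenance:", object@provenance, "\n")
})

setMethod("show", "CandidateBGC", function(object) {
    cat(sprintf("CandidateBGC %s:%s %d-%d [%s]\n", object@genomeId,
                object@contigId, object@span[1], object@span[2],
                object@verdict))
    cat(" ", nrow(object@genes), "gene(s);",
        nrow(object@precursors), "precursor candidate(s)")
    if (length(object@failReasons))
        cat("; fail:", paste(object@failReasons, collapse = ","))
    cat("\n")
})

setMethod("show", "SSNGraph", function(object) {
    cat("SSNGraph:", nrow(object@nodes), "node(s),",
        nrow(object@edges), "edge(s) at identity >=",
        object@params$identity_threshold_pct, "%\n")
})
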
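## Orchestration: mine -> physchem -> SSN -> logos/cleavage -> tree as one
## reproducible run with a counts report.

#' Pipeline run configuration
#'
#' @param genomes list of [GenomeRecord-class], or a character vector of
#'   FASTA paths (matching `.gff3` files next to them are picked up
#'   automatically).
#' @param seeds a [SeedSet-class].
#' @param out_dir output directory; `NULL` for in-memory results only.
#' @param k window half-width in genes.
#' @param params [alignParams()].
#' @param thresholds [searchThresholds()].
#' @param identity_threshold_pct SSN identity cutoff.
#' @param ssn_min_score SSN raw-score floor.
#' @param min_prec_aa,max_prec_aa precursor length bounds.
#' @param pka a [pkaTable()].
#' @param cleavage_anchors data.frame from [cleavageSiteTable()].
#' @param log_level `"info"` (one line per stage per genome) or `"quiet"`.
#' @return list of class `cm_run_config`.
#' @export
runConfig <- function(genomes, seeds = defaultSeedSet(), out_dir = NULL,
                      k = 10L, params = alignParams(),
                      thresholds = searchThresholds(),
                      identity_threshold_pct = 50, ssn_min_score = 60,
                      min_prec_aa = 25L, max_prec_aa = 150L,
                      pka = pkaTable(),
                      cleavage_anchors = cleavageSiteTable(),
                      log_level = c("info", "quiet")) {
    log_level <- match.arg(log_level)
    if (is.character(genomes)) {
        missing <- genomes[!file.exists(genomes)]
        if (length(missing))
            stop("genome FASTA not found: ", paste(missing, collapse = ", "))
    }
    stopifnot(identity_threshold_pct >= 0, identity_threshold_pct <= 100,
              k >= 1L, min_prec_aa < max_prec_aa)
    structure(list(genomes = genomes, seeds = seeds, out_dir = out_dir,
                   k = as.integer(k), params = params,
                   thresholds = thresholds,
                   identity_threshold_pct = identity_threshold_pct,
                   ssn_min_score = ssn_min_score,
                   min_prec_aa = as.integer(min_prec_aa),
                   max_prec_aa = as.integer(max_prec_aa), pka = pka,
                   cleavage_anchors = cleavage_anchors,
                   log_level = log_level),
              class = "cm_run_config")
}

.plog <- function(config, ...) {
    if (config$log_level == "info") message(...)
}

#' Run the full mining pipeline
#'
#' Stages, in order: genome mining (transporter search, windows,
#' co-occurrence filter), physicochemical profiling of the unique passing
#' precursors, sequence similarity network and group assignment, per-group
#' alignment + logo matrices + cleavage transfer (groups of >= 3 with a
#' characterized anchor where available), and the neighbor-joining tree.
#' With `out_dir` set, every intermediate is written (TSVs, aligned FASTA,
#' Newick, JSON-free plain-text report). Identical inputs and configuration
#' give identical results.
#'
#' @param config a [runConfig()].
#' @return list of class `cm_run_report`: `counts` (named integer vector:
#'   genomes_scanned, transporter_hits, windows, passing_bgcs,
#'   unique_precursors, groups, singletons, subgroup_i, subgroup_ii,
#'   subgroup_ambiguous), `bgcs`, `nodes`, `groups`, `profiles`, `logos`,
#'   `cleavage`, `tree`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "cm_run_config"))
    genomes <- config$genomes
    if (is.character(genomes)) {
        paths <- genomes
        genomes <- lapply(paths, function(p) {
            gff <- sub("\\.(fna|fa|fasta)$", ".gff3", p)
            loadAnnotatedGenome(p, if (file.exists(gff)) gff else NULL)
        })
    }
    allBgcs <- list()
    nHits <- 0L; nWindows <- 0L
    for (g in genomes) {
        res <- mineGenome(g, config$seeds, config$params, config$thresholds,
                          config$k, config$min_prec_aa, config$max_prec_aa)
        nHits <- nHits + nrow(res$transporter_hits)
        nWindows <- nWindows + res$n_windows
        allBgcs <- c(allBgcs, res$bgcs)
        .plog(config, "mine: ", genomeId(g), " -> ",
              res$n_windows, " window(s), ",
              sum(vapply(res$bgcs, function(b) verdict(b) == "pass",
                         logical(1))), " passing")
    }
    passing <- Filter(function(b) verdict(b) == "pass", allBgcs)

    precRecords <- stats::setNames(character(), character())
    for (b in passing) {
        pr <- precursors(b)
        pr <- pr[pr$support == "homology", , drop = FALSE]
        if (nrow(pr))
            precRecords <- c(precRecords, stats::setNames(
                pr$sequence, paste0(b@genomeId, "_", pr$id)))
    }
    nodes <- dedupeSequences(precRecords)
    .plog(config, "physchem/ssn: ", length(precRecords), " precursor(s), ",
          nrow(nodes), " unique")

    profiles <- if (nrow(nodes))
        physchemProfile(stats::setNames(nodes$sequence, nodes$id),
                        config$pka)
    else data.frame(id = character(), length = integer(), gravy = numeric(),
                    net_charge_pH7 = numeric(), pI_linear = numeric(),
                    pI_cyclic = numeric(), pI_linear_defined = logical(),
                    pI_cyclic_defined = logical(), subgroup = character(),
                    stringsAsFactors = FALSE)

    if (nrow(nodes)) {
        graph <- buildSSN(nodes, config$params,
                          config$identity_threshold_pct,
                          config$ssn_min_score)
        groups <- assignGroups(graph)
    } else {
        graph <- NULL
        groups <- data.frame(id = character(), group_id = integer(),
                             group_size = integer(), is_singleton = logical(),
                             stringsAsFactors = FALSE)
    }

    logos <- list(); cleavage <- list(); msas <- list()
    gids <- sort(unique(stats::na.omit(groups$group_id)))
    for (g in gids) {
        ids <- groups$id[!is.na(groups$group_id) & groups$group_id == g]
        if (length(ids) < 3L) next  # logos for groups of three or more
        seqsG <- stats::setNames(nodes$sequence[match(ids, nodes$id)], ids)
        msa <- alignMsa(seqsG, config$params)
        msas[[as.character(g)]] <- msa
        logos[[as.character(g)]] <- logoMatrix(msa)
        anch <- config$cleavage_anchors
        hit <- which(anch$seed_id %in% ids)
        if (length(hit))
            cleavage[[as.character(g)]] <- transferCleavage(
                msa, anch$seed_id[hit[1L]], anch$leader_length[hit[1L]])
    }
    .plog(config, "logo/cleavage: ", length(logos), " group logo(s), ",
          length(cleavage), " cleavage table(s)")

    tree <- NULL
    if (nrow(nodes) >= 3L) {
        D <- distanceMatrix(stats::setNames(nodes$sequence, nodes$id),
                            config$params)
        ann <- data.frame(id = nodes$id,
                          group_id = groups$group_id[match(nodes$id,
                                                           groups$id)],
                          subgroup = profiles$subgroup[match(nodes$id,
                                                             profiles$id)],
                          gravy = profiles$gravy[match(nodes$id,
                                                       profiles$id)],
                          stringsAsFactors = FALSE)
        tree <- njTree(D, annotations = ann)
        .plog(config, "tree: ", nrow(nodes), " leaves")
    }

    counts <- c(genomes_scanned = length(genomes),
                transporter_hits = nHits,
                windows = nWindows,
                passing_bgcs = length(passing),
                unique_precursors = nrow(nodes),
                groups = length(unique(stats::na.omit(groups$group_id))),
                singletons = sum(groups$is_singleton),
                subgroup_i = sum(profiles$subgroup == "i"),
                subgroup_ii = sum(profiles$subgroup == "ii"),
                subgroup_ambiguous = sum(profiles$subgroup == "ambiguous"))
    counts <- vapply(counts, as.integer, integer(1))

    report <- structure(list(counts = counts, bgcs = allBgcs, nodes = nodes,
                             groups = groups, profiles = profiles,
                             graph = graph, logos = logos, msas = msas,
                             cleavage = cleavage, tree = tree),
                        class = "cm_run_report")

    if (!is.null(config$out_dir)) {
        od <- config$out_dir
        dir.create(od, recursive = TRUE, showWarnings = FALSE)
        if (!is.null(graph))
            writeEdgeList(graph, file.path(od, "ssn"), groups, profiles)
        writeResultsTables(allBgcs, nodes, groups, profiles, od)
        for (g in names(msas)) {
            writeMsa(msas[[g]], file.path(od, sprintf("group%s.afa", g)))
            writeLogoMatrix(logos[[g]],
                            file.path(od, sprintf("group%s_logo.tsv", g)))
        }
        if (!is.null(tree))
            writeTree(tree, file.path(od, "precursors.nwk"),
                      file.path(od, "leaf_annotations.tsv"))
        rpt <- data.frame(stage = names(counts),
                          count = unname(counts))
        utils::write.table(rpt, file.path(od, "report.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    report
}

#' @export
print.cm_run_report <- function(x, ...) {
    cat("cycloMiner run report\n")
    for (nm in names(x$counts))
        cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
    invisible(x)
}
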
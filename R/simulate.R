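## Synthetic annotated genomes with implanted, ground-truthed bacteriocin
## clusters and decoys. The generator emulates the cluster architectures seen
## in real producers (1-3 precursor copies, a SpoIIM gene, 1-3 transporters,
## optional Yip1/transposase/peptidase accessories) at controlled divergence
## from the seed proteins, plus negative decoy neighborhoods missing one
## required role.

#' One cluster (or decoy) specification
#'
#' @param bacteriocin seed family to implant (a `bacteriocin` name in the
#'   seed set).
#' @param n_precursors,n_transporters copy numbers (1-3).
#' @param include_spoiim,include_yip1,include_transposase,include_peptidase
#'   architecture toggles.
#' @param identity target percent identity to the seed for transporter and
#'   SpoIIM genes (20-100).
#' @param precursor_identity target identity for precursor copies; defaults
#'   to `identity`.
#' @param precursor_annotation `"annotated"` (CDS in the GFF3) or
#'   `"unannotated"` (omitted from the GFF3; truth only in the manifest).
#' @param omit_role `NULL`, or one of `"precursor"`, `"spoIIM"`,
#'   `"transporter"`: turns the cluster into a decoy missing that role.
#' @param precursor_mutation_order optional integer permutation of the seed
#'   precursor positions; when given, the mutated positions are the first k
#'   of this order (nested divergence ladder along a lineage, keeping family
#'   members mutually similar).
#' @return list of class `cm_cluster_spec`.
#' @export
clusterSpec <- function(bacteriocin, n_precursors = 1L, n_transporters = 1L,
                        include_spoiim = TRUE, include_yip1 = FALSE,
                        include_transposase = FALSE,
                        include_peptidase = FALSE, identity = 80,
                        precursor_identity = identity,
                        precursor_annotation = c("annotated", "unannotated"),
                        omit_role = NULL,
                        precursor_mutation_order = NULL) {
    precursor_annotation <- match.arg(precursor_annotation)
    stopifnot(n_precursors %in% 1:3, n_transporters %in% 1:3,
              identity >= 20, identity <= 100,
              precursor_identity >= 20, precursor_identity <= 100)
    if (!is.null(omit_role))
        stopifnot(omit_role %in% c("precursor", "spoIIM", "transporter"))
    structure(list(bacteriocin = bacteriocin,
                   n_precursors = as.integer(n_precursors),
                   n_transporters = as.integer(n_transporters),
                   include_spoiim = include_spoiim,
                   include_yip1 = include_yip1,
                   include_transposase = include_transposase,
                   include_peptidase = include_peptidase,
                   identity = identity,
                   precursor_identity = precursor_identity,
                   precursor_annotation = precursor_annotation,
                   omit_role = omit_role,
                   precursor_mutation_order = precursor_mutation_order),
              class = "cm_cluster_spec")
}

#' Simulation configuration
#'
#' @param seed RNG seed (mandatory; full determinism under a fixed seed).
#' @param genome_id genome identifier.
#' @param clusters list of [clusterSpec()] (may be empty).
#' @param n_background background gene count.
#' @param background_len_aa inclusive range of background protein lengths
#'   (default 180-420 aa, typical bacterial CDS sizes and safely above the
#'   precursor length bounds).
#' @param spacer_nt inclusive range of intergenic spacer lengths.
#' @param seeds the [SeedSet-class] to implant from.
#' @return list of class `cm_sim_config`.
#' @export
simConfig <- function(seed, genome_id = "simg1", clusters = list(),
                      n_background = 12L,
                      background_len_aa = c(180L, 420L),
                      spacer_nt = c(20L, 200L), seeds = defaultSeedSet()) {
    stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1L,
              n_background >= 0L)
    for (cl in clusters) stopifnot(inherits(cl, "cm_cluster_spec"))
    structure(list(seed = as.integer(seed), genome_id = genome_id,
                   clusters = clusters, n_background = as.integer(n_background),
                   background_len_aa = as.integer(background_len_aa),
                   spacer_nt = as.integer(spacer_nt), seeds = seeds),
              class = "cm_sim_config")
}

#' Mutate a protein to a target identity
#'
#' Substitution-only divergence: `k = round(L * (1 - target/100))` positions
#' are chosen without replacement (or taken as the first k of
#' `mutation_order`), and each is replaced by a residue drawn with
#' probability proportional to `2^(s/2)` over the substitution scores `s`
#' against the original residue, the original excluded. Length is preserved.
#' Uses the current R RNG stream; seed it for reproducibility.
#'
#' For very short sequences the attainable identity grid is coarse; the
#' realized identity (measured by global alignment) may fall outside +-3
#' points of the target, in which case a warning is raised and the best
#' effort returned.
#'
#' @param protein input sequence.
#' @param target_identity_pct 20-100.
#' @param mutation_order optional permutation of `1:nchar(protein)`.
#' @param params [alignParams()] (exchangeability weights + verification).
#' @return the mutated sequence, with attribute `realized_identity`.
#' @export
mutateToIdentity <- function(protein, target_identity_pct,
                             mutation_order = NULL,
                             params = alignParams()) {
    stopifnot(target_identity_pct >= 20, target_identity_pct <= 100)
    .checkProtein(protein)
    L <- nchar(protein)
    k <- round(L * (1 - target_identity_pct / 100))
    if (k == 0L) {
        out <- protein
        if (100 - target_identity_pct > 3)
            warning(sprintf(
                "realized identity 100.0 outside +-3 of target %.1f (length %d)",
                target_identity_pct, L))
        attr(out, "realized_identity") <- 100
        return(out)
    }
    pos <- if (!is.null(mutation_order)) {
        stopifnot(length(mutation_order) >= k)
        mutation_order[seq_len(k)]
    } else sample.int(L, k)
    res <- strsplit(protein, "")[[1]]
    canon <- AA_ALPHABET21[1:20]
    nested <- !is.null(mutation_order)
    for (p in pos) {
        orig <- res[p]
        alt <- setdiff(canon, orig)
        w <- 2^(params$matrix[orig, alt] / 2)
        if (nested) {
            # deterministic per-position choice so that ladder members agree
            # wherever both are mutated (true nested divergence)
            u <- (p * 0.6180339887498949) %% 1
            res[p] <- alt[findInterval(u * sum(w), cumsum(w)) + 1L]
        } else {
            res[p] <- sample(alt, 1L, prob = w)
        }
    }
    out <- paste(res, collapse = "")
    realized <- alignGlobal(protein, out, params)
    realized <- 100 * realized$n_identical / realized$n_aligned_columns
    if (abs(realized - target_identity_pct) > 3)
        warning(sprintf(
            "realized identity %.1f outside +-3 of target %.1f (length %d)",
            realized, target_identity_pct, L))
    attr(out, "realized_identity") <- realized
    out
}

# mutate a gene product, forcing the initiator methionine: the genetic code
# folds every initiator codon to M on translation, so any other first
# residue could never round-trip through the emitted CDS
.mutateGene <- function(protein, target, mutation_order = NULL,
                        params = alignParams()) {
    out <- suppressWarnings(
        mutateToIdentity(protein, target, mutation_order, params))
    if (substr(out, 1L, 1L) != "M") {
        fixed <- paste0("M", substr(out, 2L, nchar(out)))
        al <- alignGlobal(protein, fixed, params)
        attr(fixed, "realized_identity") <-
            100 * al$n_identical / al$n_aligned_columns
        out <- fixed
    }
    out
}

# uniform reverse translation under the bacterial code; start codon fixed to
# ATG, one stop appended
.codonTable <- function() {
    if (is.null(.cm_cache$codons)) {
        gc <- .geneticCode11()
        .cm_cache$codons <- split(names(gc), unname(gc))
    }
    .cm_cache$codons
}

.reverseTranslate <- function(protein) {
    tab <- .codonTable()
    res <- strsplit(protein, "")[[1]]
    codons <- vapply(seq_along(res), function(i) {
        if (i == 1L && res[i] == "M") return("ATG")
        opts <- tab[[res[i]]]
        opts[sample.int(length(opts), 1L)]
    }, character(1))
    paste0(paste(codons, collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
}

.randomProtein <- function(len) {
    paste0("M", paste(sample(AA_ALPHABET21[1:20], len - 1L, replace = TRUE),
                      collapse = ""))
}

.randomDNA <- function(len) {
    if (len <= 0L) return("")
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate one synthetic annotated genome
#'
#' Emits a single-contig genome: background genes and the configured
#' cluster/decoy cassettes in random order, separated by random intergenic
#' spacers. Cluster proteins are seed proteins mutated to the target
#' identity and reverse-translated with uniform codon choice; an in-frame
#' stop codon guards the 5' side of every CDS so the ORF scanner recovers
#' unannotated precursors at their exact coordinates. Ground truth goes in
#' the manifest.
#'
#' @param config a [simConfig()].
#' @param out_dir optional directory; when given, writes `<genome_id>.fna`,
#'   `<genome_id>.gff3` and `<genome_id>_manifest.tsv`.
#' @return list: `genome` ([GenomeRecord-class]), `manifest` (data.frame:
#'   element, role, seed_id, start, end, strand, target_identity,
#'   realized_identity, annotated, sequence).
#' @export
generateGenome <- function(config, out_dir = NULL) {
    stopifnot(inherits(config, "cm_sim_config"))
    set.seed(config$seed)
    seeds <- config$seeds
    info <- as.data.frame(seedInfo(seeds))
    seqs <- as.character(seedSequences(seeds))

    pickSeed <- function(bact, role) {
        i <- which(info$bacteriocin == bact & info$role == role)
        if (!length(i)) {
            i <- which(info$role == role)  # family without its own entry
            if (!length(i))
                stop("seed set has no entry for role '", role,
                     "' required by the architecture")
            i <- i[1L]
        }
        list(id = info$id[i[1L]], seq = seqs[[i[1L]]])
    }

    # assemble gene cassettes: list(dna, genes=data.frame(relative coords))
    cassettes <- list()
    manifest <- list()
    addCassette <- function(protein, id, product, strand, element, role,
                            seed_id, target_id, realized_id, annotated) {
        cds <- .reverseTranslate(protein)
        len <- nchar(cds)
        if (strand == "+") {
            dna <- paste0("TAA", cds)
            cdsStart <- 4L; cdsEnd <- len + 3L
        } else {
            dna <- .revcomp(paste0("TAA", cds))
            cdsStart <- 1L; cdsEnd <- len
        }
        cassettes[[length(cassettes) + 1L]] <<- list(
            dna = dna,
            gene = data.frame(id = id, product = product, strand = strand,
                              relStart = cdsStart, relEnd = cdsEnd,
                              annotated = annotated,
                              stringsAsFactors = FALSE),
            truth = data.frame(element = element, role = role,
                               seed_id = seed_id,
                               target_identity = target_id,
                               realized_identity = realized_id,
                               annotated = annotated, sequence = protein,
                               id = id, strand = strand,
                               stringsAsFactors = FALSE))
    }

    gidx <- 0L
    nextId <- function(prefix) {
        gidx <<- gidx + 1L
        sprintf("%s_%s%03d", config$genome_id, prefix, gidx)
    }

    for (bi in seq_len(config$n_background)) {
        len <- sample(config$background_len_aa[1]:config$background_len_aa[2],
                      1L)
        addCassette(.randomProtein(len), nextId("bg"),
                    "hypothetical protein", sample(c("+", "-"), 1L),
                    element = "background", role = "background",
                    seed_id = NA, target_id = NA, realized_id = NA,
                    annotated = TRUE)
    }

    clusterCassettes <- list()
    for (ci in seq_along(config$clusters)) {
        cl <- config$clusters[[ci]]
        element <- sprintf("%s%d",
                           if (is.null(cl$omit_role)) "cluster" else "decoy",
                           ci)
        strand <- sample(c("+", "-"), 1L)
        genes <- list()
        omit <- function(role) !is.null(cl$omit_role) &&
            identical(cl$omit_role, role)
        if (!omit("precursor")) {
            sd <- pickSeed(cl$bacteriocin, "precursor")
            for (p in seq_len(cl$n_precursors)) {
                mut <- .mutateGene(sd$seq, cl$precursor_identity,
                                   cl$precursor_mutation_order)
                genes[[length(genes) + 1L]] <- list(
                    protein = as.character(mut), role = "precursor",
                    seed_id = sd$id, target = cl$precursor_identity,
                    realized = attr(mut, "realized_identity"),
                    annotated = cl$precursor_annotation == "annotated",
                    product = "bacteriocin precursor peptide")
            }
        }
        if (cl$include_spoiim && !omit("spoIIM")) {
            sd <- pickSeed(cl$bacteriocin, "spoIIM")
            mut <- .mutateGene(sd$seq, cl$identity)
            genes[[length(genes) + 1L]] <- list(
                protein = as.character(mut), role = "spoIIM",
                seed_id = sd$id, target = cl$identity,
                realized = attr(mut, "realized_identity"), annotated = TRUE,
                product = "stage II sporulation protein M")
        }
        if (!omit("transporter")) {
            sd <- pickSeed(cl$bacteriocin, "transporter")
            for (p in seq_len(cl$n_transporters)) {
                mut <- .mutateGene(sd$seq, cl$identity)
                genes[[length(genes) + 1L]] <- list(
                    protein = as.character(mut), role = "transporter",
                    seed_id = sd$id, target = cl$identity,
                    realized = attr(mut, "realized_identity"),
                    annotated = TRUE, product = "ABC transporter")
            }
        }
        if (cl$include_yip1) {
            sd <- pickSeed(cl$bacteriocin, "yip1")
            mut <- .mutateGene(sd$seq, cl$identity)
            genes[[length(genes) + 1L]] <- list(
                protein = as.character(mut), role = "yip1", seed_id = sd$id,
                target = cl$identity,
                realized = attr(mut, "realized_identity"), annotated = TRUE,
                product = "Yip1 family membrane protein")
        }
        if (cl$include_peptidase) {
            sd <- pickSeed(cl$bacteriocin, "peptidase")
            mut <- .mutateGene(sd$seq, cl$identity)
            genes[[length(genes) + 1L]] <- list(
                protein = as.character(mut), role = "peptidase",
                seed_id = sd$id, target = cl$identity,
                realized = attr(mut, "realized_identity"), annotated = TRUE,
                product = "M48 family zinc metallopeptidase")
        }
        if (cl$include_transposase) {
            genes[[length(genes) + 1L]] <- list(
                protein = .randomProtein(240L), role = "transposase",
                seed_id = NA, target = NA, realized = NA, annotated = TRUE,
                product = "IS200-like transposase")
        }
        # one cassette holding the whole cluster, genes in listed order
        dnaParts <- character(); geneRows <- list(); truthRows <- list()
        offset <- 0L
        for (g in genes) {
            cds <- .reverseTranslate(g$protein)
            len <- nchar(cds)
            if (strand == "+") {
                part <- paste0("TAA", cds)
                rs <- offset + 4L; re <- offset + len + 3L
            } else {
                part <- .revcomp(paste0("TAA", cds))
                rs <- offset + 1L; re <- offset + len
            }
            gid <- nextId(substr(g$role, 1L, 3L))
            dnaParts <- c(dnaParts, part)
            geneRows[[length(geneRows) + 1L]] <- data.frame(
                id = gid, product = g$product, strand = strand,
                relStart = rs, relEnd = re, annotated = g$annotated,
                stringsAsFactors = FALSE)
            truthRows[[length(truthRows) + 1L]] <- data.frame(
                element = element, role = g$role, seed_id = g$seed_id,
                target_identity = g$target, realized_identity = g$realized,
                annotated = g$annotated, sequence = g$protein, id = gid,
                strand = strand, stringsAsFactors = FALSE)
            offset <- offset + nchar(part) +
                sample(config$spacer_nt[1]:config$spacer_nt[2], 1L)
            dnaParts <- c(dnaParts,
                          .randomDNA(offset - sum(nchar(dnaParts))))
        }
        cassettes[[length(cassettes) + 1L]] <- list(
            dna = paste(dnaParts, collapse = ""),
            gene = do.call(rbind, geneRows),
            truth = do.call(rbind, truthRows))
    }

    # shuffle cassette order, join with spacers
    ord <- sample(seq_along(cassettes))
    dna <- ""
    geneRows <- list(); truthRows <- list()
    for (ii in ord) {
        cs <- cassettes[[ii]]
        spacer <- .randomDNA(sample(config$spacer_nt[1]:config$spacer_nt[2],
                                    1L))
        base <- nchar(dna) + nchar(spacer)
        dna <- paste0(dna, spacer, cs$dna)
        g <- cs$gene
        g$start <- g$relStart + base
        g$end <- g$relEnd + base
        geneRows[[length(geneRows) + 1L]] <- g
        if (!is.null(cs$truth)) {
            tr <- cs$truth
            tr$start <- g$start[match(tr$id, g$id)]
            tr$end <- g$end[match(tr$id, g$id)]
            truthRows[[length(truthRows) + 1L]] <- tr
        }
    }
    dna <- paste0(dna, .randomDNA(sample(config$spacer_nt[1]:
                                             config$spacer_nt[2], 1L)))
    emptyGene <- data.frame(id = character(), product = character(),
                            strand = character(), relStart = integer(),
                            relEnd = integer(), annotated = logical(),
                            start = integer(), end = integer(),
                            stringsAsFactors = FALSE)
    genes <- if (length(geneRows)) do.call(rbind, geneRows) else emptyGene
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
        data.frame(element = character(), role = character(),
                   seed_id = character(), target_identity = numeric(),
                   realized_identity = numeric(), annotated = logical(),
                   sequence = character(), id = character(),
                   strand = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
    contigId <- paste0(config$genome_id, "_c1")

    ann <- genes[genes$annotated, , drop = FALSE]
    ann <- ann[order(ann$start), , drop = FALSE]
    contigs <- Biostrings::DNAStringSet(stats::setNames(dna, contigId))
    feats <- GenomicRanges::GRanges()
    if (nrow(ann)) {
        feats <- GenomicRanges::GRanges(
            seqnames = contigId,
            ranges = IRanges::IRanges(ann$start, ann$end),
            strand = ann$strand)
        protein <- character(nrow(ann)); prem <- logical(nrow(ann))
        for (i in seq_len(nrow(ann))) {
            cds <- substr(dna, ann$start[i], ann$end[i])
            if (ann$strand[i] == "-") cds <- .revcomp(cds)
            tr <- .translateCDS(cds)
            protein[i] <- tr$protein; prem[i] <- tr$premature_stop
        }
        S4Vectors::mcols(feats) <- S4Vectors::DataFrame(
            feature_kind = "CDS", protein_id = ann$id,
            product = ann$product, protein = protein,
            premature_stop = prem)
    }
    genome <- methods::new("GenomeRecord", genomeId = config$genome_id,
                           contigs = contigs, features = feats)
    truth <- truth[truth$element != "background", , drop = FALSE]
    manifest <- data.frame(
        genome_id = rep(config$genome_id, nrow(truth)),
        contig_id = rep(contigId, nrow(truth)),
        truth[, c("element", "role", "seed_id", "id", "start", "end",
                  "strand", "target_identity", "realized_identity",
                  "annotated", "sequence")],
        stringsAsFactors = FALSE)
    rownames(manifest) <- NULL

    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        writeGenome(genome,
                    file.path(out_dir, paste0(config$genome_id, ".fna")),
                    file.path(out_dir, paste0(config$genome_id, ".gff3")))
        utils::write.table(manifest,
                           file.path(out_dir, paste0(config$genome_id,
                                                     "_manifest.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(genome = genome, manifest = manifest)
}

#' Simulate the benchmark study set
#'
#' The standard recovery scenario used by the package's validation: 20
#' genomes comprising 6 complete clusters (transporter/SpoIIM identity
#' ladder 60-90%; five precursors on a nested divergence ladder 60-90% from
#' one seed family so they stay mutually >= 50% identical, plus one outlier
#' precursor implanted at 40% identity that the network must separate),
#' 4 decoys (two missing the precursor, two missing SpoIIM), and 10
#' background-only genomes.
#'
#' @param seed RNG seed.
#' @param seeds seed set to implant from.
#' @param out_dir optional directory for FASTA/GFF3/manifest files.
#' @return list: `genomes` (list of [GenomeRecord-class]), `manifest`
#'   (combined data.frame), `truth` (list: complete/decoy genome ids).
#' @export
simulateBenchmarkSet <- function(seed, seeds = defaultSeedSet(),
                                 out_dir = NULL) {
    set.seed(seed)
    info <- as.data.frame(seedInfo(seeds))
    precSeqs <- as.character(seedSequences(seeds, "precursor"))
    famA <- info$bacteriocin[info$role == "precursor"][1L]
    famASeq <- precSeqs[[which(info$role == "precursor")[1L]]]
    orderA <- sample.int(nchar(famASeq))
    ladder <- c(90, 82.5, 75, 67.5, 60)
    specs <- list()
    for (i in seq_along(ladder))
        specs[[i]] <- clusterSpec(famA, identity = 60 + (i - 1) * 6,
                                  precursor_identity = ladder[i],
                                  precursor_mutation_order = orderA,
                                  n_precursors = if (i == 1L) 2L else 1L,
                                  include_yip1 = i <= 2L,
                                  include_transposase = i == 3L)
    specs[[6L]] <- clusterSpec(famA, identity = 90,
                               precursor_identity = 40)
    decoys <- list(
        clusterSpec(famA, identity = 80, omit_role = "precursor"),
        clusterSpec(famA, identity = 70, omit_role = "precursor"),
        clusterSpec(famA, identity = 80, omit_role = "spoIIM"),
        clusterSpec(famA, identity = 70, omit_role = "spoIIM"))
    genomes <- list(); manifests <- list()
    completeIds <- character(); decoyIds <- character()
    gseed <- sample.int(1e6, 20L)
    for (i in 1:20) {
        gid <- sprintf("simg%02d", i)
        cl <- if (i <= 6) list(specs[[i]]) else if (i <= 10)
            list(decoys[[i - 6L]]) else list()
        if (i <= 6) completeIds <- c(completeIds, gid)
        if (i > 6 && i <= 10) decoyIds <- c(decoyIds, gid)
        cfg <- simConfig(seed = gseed[i], genome_id = gid, clusters = cl,
                         seeds = seeds)
        res <- generateGenome(cfg, out_dir = out_dir)
        genomes[[gid]] <- res$genome
        manifests[[gid]] <- res$manifest
    }
    list(genomes = genomes,
         manifest = do.call(rbind, manifests),
         truth = list(complete = completeIds, decoy = decoyIds))
}
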
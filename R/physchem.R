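## Peptide physicochemistry: Kyte-Doolittle GRAVY, Henderson-Hasselbalch net
## charge, isoelectric point by bisection, and the subgroup i/ii classifier.

# Kyte & Doolittle hydropathy values
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Ionizable-group pKa table
#'
#' Defaults are the EMBOSS values (side chains C 8.5, D 3.9, E 4.1, H 6.5,
#' K 10.8, R 12.5, Y 10.1; termini: alpha-amino 8.6, alpha-carboxyl 3.6).
#' All values must lie in (0, 14).
#'
#' @param C,D,E,H,K,R,Y side-chain pKa values.
#' @param nterm,cterm terminal-group pKa values.
#' @return named numeric vector of class `cm_pka_table`.
#' @export
pkaTable <- function(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5,
                     Y = 10.1, nterm = 8.6, cterm = 3.6) {
    v <- c(C = C, D = D, E = E, H = H, K = K, R = R, Y = Y,
           nterm = nterm, cterm = cterm)
    stopifnot(all(v > 0 & v < 14))
    structure(v, class = "cm_pka_table")
}

.countedResidues <- function(sequence) {
    .checkProtein(sequence)
    r <- strsplit(sequence, "")[[1]]
    if (!all(r %in% AA_ALPHABET21))
        stop("invalid residue(s): ",
             paste(unique(setdiff(r, AA_ALPHABET21)), collapse = ","))
    r
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence. `X` residues are
#' excluded from both the sum and the length.
#'
#' @param sequence protein string.
#' @return dimensionless value in \[-4.5, 4.5\].
#' @examples
#' gravy("AAAA")  # 1.8
#' gravy("GGGG")  # -0.4
#' @export
gravy <- function(sequence) {
    r <- .countedResidues(sequence)
    r <- r[r != "X"]
    if (!length(r)) stop("GRAVY undefined: no canonical residues")
    mean(.KD[r])
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch summation: each basic group (R, K, H and, in linear
#' mode, the alpha-amino terminus) contributes `+1/(1 + 10^(pH - pKa))`; each
#' acidic group (D, E, C, Y and, in linear mode, the alpha-carboxyl terminus)
#' contributes `-1/(1 + 10^(pKa - pH))`. Cyclic mode drops both terminal
#' groups (head-to-tail amide bond consumes them).
#'
#' @param sequence protein string.
#' @param pH in (0, 14).
#' @param mode `"linear"` or `"cyclic"`.
#' @param pka a [pkaTable()].
#' @return net charge in elementary charges.
#' @export
netCharge <- function(sequence, pH = 7, mode = c("linear", "cyclic"),
                      pka = pkaTable()) {
    mode <- match.arg(mode)
    stopifnot(pH > 0, pH < 14)
    r <- .countedResidues(sequence)
    cnt <- table(factor(r, levels = AA_ALPHABET21))
    pos <- 0
    for (res in c("R", "K", "H"))
        pos <- pos + cnt[[res]] / (1 + 10^(pH - pka[[res]]))
    neg <- 0
    for (res in c("D", "E", "C", "Y"))
        neg <- neg + cnt[[res]] / (1 + 10^(pka[[res]] - pH))
    if (mode == "linear") {
        pos <- pos + 1 / (1 + 10^(pH - pka[["nterm"]]))
        neg <- neg + 1 / (1 + 10^(pka[["cterm"]] - pH))
    }
    pos - neg
}

#' Isoelectric point by bisection
#'
#' The pH at which [netCharge()] crosses zero, located by bisection on
#' \[0.001, 13.999\] to a tolerance of 1e-4 pH units. The charge curve is
#' strictly decreasing in pH, so the zero is unique when it exists. Peptides
#' whose charge never changes sign on the interval (e.g. a cyclic peptide
#' with only basic residues) have no isoelectric point: `defined = FALSE`.
#'
#' @inheritParams netCharge
#' @param tol bisection tolerance in pH units.
#' @return list: `pI` (numeric or `NA`), `defined` (logical).
#' @export
isoelectricPoint <- function(sequence, mode = c("linear", "cyclic"),
                             pka = pkaTable(), tol = 1e-4) {
    mode <- match.arg(mode)
    lo <- 0.001; hi <- 13.999
    f <- function(p) netCharge(sequence, p, mode, pka)
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || flo * fhi > 0 || (flo == 0 && fhi == 0))
        return(list(pI = NA_real_, defined = FALSE))
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (fm > 0) lo <- mid else hi <- mid
    }
    list(pI = (lo + hi) / 2, defined = TRUE)
}

#' Subgroup i / ii classification of a core peptide
#'
#' Charge-based rule computed on the mature (cyclic) core: subgroup i
#' (cationic) when the cyclic net charge at pH 7 is at least `+2`; subgroup
#' ii (neutral, hydrophobic) when the charge lies in \[-1, +1\] and GRAVY is
#' non-negative; anything else is `ambiguous`. Charge rather than pI drives
#' the call because cyclic peptides without acidic residues have no defined
#' pI.
#'
#' @param core_sequence mature core peptide.
#' @param charge_i minimum cyclic net charge for subgroup i.
#' @param charge_ii_band inclusive charge band for subgroup ii.
#' @param gravy_ii minimum GRAVY for subgroup ii.
#' @param pka a [pkaTable()].
#' @return `"i"`, `"ii"` or `"ambiguous"`.
#' @export
classifySubgroup <- function(core_sequence, charge_i = 2,
                             charge_ii_band = c(-1, 1), gravy_ii = 0,
                             pka = pkaTable()) {
    z <- netCharge(core_sequence, 7, "cyclic", pka)
    g <- gravy(core_sequence)
    if (z >= charge_i) return("i")
    if (z >= charge_ii_band[1] && z <= charge_ii_band[2] && g >= gravy_ii)
        return("ii")
    "ambiguous"
}

#' Physicochemical profile of peptides
#'
#' GRAVY, net charge at pH 7 (cyclic), linear and cyclic isoelectric points,
#' length and the subgroup call, one row per peptide.
#'
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   core peptides.
#' @param pka a [pkaTable()].
#' @return data.frame: `id`, `length`, `gravy`, `net_charge_pH7`,
#'   `pI_linear`, `pI_cyclic`, `pI_linear_defined`, `pI_cyclic_defined`,
#'   `subgroup`.
#' @export
physchemProfile <- function(sequences, pka = pkaTable()) {
    sequences <- .asNamedProteins(sequences, "sequences")
    rows <- lapply(seq_along(sequences), function(i) {
        s <- sequences[[i]]
        pl <- isoelectricPoint(s, "linear", pka)
        pc <- isoelectricPoint(s, "cyclic", pka)
        data.frame(id = names(sequences)[i],
                   length = nchar(s),
                   gravy = gravy(s),
                   net_charge_pH7 = netCharge(s, 7, "cyclic", pka),
                   pI_linear = pl$pI, pI_cyclic = pc$pI,
                   pI_linear_defined = pl$defined,
                   pI_cyclic_defined = pc$defined,
                   subgroup = classifySubgroup(s, pka = pka),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
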
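---
title: "Transporter-guided mining for head-to-tail cyclized bacteriocins: methods and design"
author: "cycloMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transporter-guided mining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloMiner)
```

## The problem

Head-to-tail cyclized (circular) bacteriocins are ribosomally synthesized
antimicrobial peptides whose N- and C-terminal residues are joined by an
amide bond after an N-terminal leader peptide is cleaved. Their biosynthetic
gene clusters (BGCs) reliably carry at least three genes: the precursor
peptide, one or more ABC-transporter components, and a SpoIIM (formerly
DUF95) membrane protein. Because precursors are short and poorly annotated,
searching genomes with *transporter* proteins of characterized circular
bacteriocins — and then demanding the precursor/SpoIIM/transporter
co-occurrence in the genomic neighborhood — finds clusters that
precursor-based searches miss.

cycloMiner implements that strategy end to end on local, annotated genomes:

1. **Homology search**: characterized transporter seeds against the genome
   proteome (Smith–Waterman, BLOSUM62, affine gaps).
2. **Neighborhood screening**: a window of `k` genes (default 10) around
   each transporter hit; role annotation of every window protein against the
   seed set; six-frame small-ORF scanning for unannotated precursors; the
   three-gene co-occurrence verdict.
3. **Physicochemistry**: GRAVY, net charge, isoelectric point of each
   candidate core peptide; classification into the cationic (subgroup i) and
   neutral/hydrophobic (subgroup ii) classes.
4. **Sequence similarity network (SSN)**: all-by-all local alignment of the
   unique precursors; edges at ≥50% identity; connected components are the
   groups, ranked by size.
5. **Group summaries**: progressive multiple alignment, sequence-logo
   matrices (information content in bits), and leader-cleavage-site transfer
   from characterized anchors.
6. **Phylogeny**: neighbor-joining on global-alignment distances with
   group/subgroup/GRAVY leaf annotations.

## Alignment model

`alignLocal()`/`alignGlobal()` implement the Gotoh affine-gap dynamic
program. Defaults mirror protein-BLAST: BLOSUM62, gap open 11, gap extend 1,
where a gap of length $L$ costs $11 + (L-1)\cdot 1$. Percent identity is
computed BLAST-style over all aligned columns, gap columns included in the
denominator; this convention matters near the 50% SSN cutoff and is fixed
package-wide. `X` scores zero against everything, so ambiguous translations
neither attract nor repel alignments. Tie-breaking is deterministic
(diagonal over up over left in the traceback; smallest end coordinates among
equal-scoring local cells), so identical inputs always give identical
output.

There is no E-value machinery: E-values parameterize a database context the
local pipeline does not have. Search uses explicit thresholds
(`searchThresholds()`: identity ≥ 30%, query coverage ≥ 0.5, raw score ≥ 50
by default).

## The co-occurrence filter

A window passes exactly when it holds (i) a homology-supported precursor
candidate, (ii) a SpoIIM homolog, and (iii) a transporter. Each gene carries
at most one role, assigned by its best passing hit with the priority
precursor > SpoIIM > transporter on ties — precursors are the scarce signal.
Accessory families are reported as flags only (Yip1 and peptidases by seed
homology; transposases by annotation text, since no closed seed role exists
for them) and never influence the verdict: the literature reports them as
recurrent features of these clusters, not as requirements.

**Precursor candidacy.** A window protein or scanned ORF of 25–150 aa is a
candidate if it aligns to a seed precursor at or above the identity
threshold (`support = "homology"`), or, failing that, if it merely *looks*
like a precursor (GRAVY ≥ −0.5; `support = "heuristic"`). Heuristic
candidates are kept in the output for bioprospecting — a genuinely novel
family has no seed to match — but they do not satisfy the verdict: roughly
half of random small ORFs pass the GRAVY screen, so a heuristic-only verdict
would accept essentially any neighborhood that happens to contain a spacer
ORF, and the screen would stop discriminating. With homology-gated verdicts
the filter keeps perfect specificity on decoy neighborhoods while retaining
full sensitivity down to the search threshold.

**ORF scanning.** All six frames of the window DNA, starts ATG/GTG/TTG, end
at the first in-frame stop, translated length within the precursor bounds;
per stop and frame only the longest qualifying ORF is kept. ORFs wholly
inside an annotated same-strand CDS are suppressed, as are (by default)
shadow ORFs overlapping annotated CDS on either strand over more than half
their length — the antisense interior of a real gene is not a credible
peptide gene, and without this rule decoy neighborhoods accumulate spurious
candidates. The precursor length bounds (25–150 aa) cover the characterized
range: leaders of 2–48 residues plus cores of roughly 33–70.

## Physicochemistry and the subgroup rule

GRAVY is the mean Kyte–Doolittle hydropathy (`X` excluded). Net charge is
the Henderson–Hasselbalch sum over ionizable side chains (EMBOSS pKa set by
default: C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1; termini 8.6 and
3.6; swappable via `pkaTable()`); cyclic mode drops both terminal groups,
because the head-to-tail amide bond consumes them. The isoelectric point is
found by bisection on [0.001, 13.999] to 1e−4 pH; the charge curve is
strictly decreasing, so the zero is unique — and genuinely absent for cyclic
peptides without acidic groups, which is why `isoelectricPoint()` returns an
explicit `defined` flag rather than a number.

Classification uses charge, not pI: subgroup i (cationic) at cyclic net
charge ≥ +2 at pH 7; subgroup ii (neutral, hydrophobic) at charge in
[−1, +1] with GRAVY ≥ 0; otherwise `ambiguous`. A pI rule ("generally
>10") would be undefined exactly where subgroup i peptides live (no acidic
residues, no zero crossing). The thresholds reproduce all 19 bundled
characterized labels and are configurable.

## The SSN and its thresholds

Nodes are unique precursor sequences (exact-string deduplication;
multiplicity preserved). Edges require both ≥50% identity and a raw score
floor, default 60. The floor is the local-search analog of the E-value
pre-filter used by database SSN tools, calibrated by inverting the
Karlin–Altschul relation $E = Kmn e^{-\lambda S}$ at peptide scale
($K=0.041$, $\lambda=0.267$, $m=n\approx 60$, $E=10^{-5}$ gives $S\approx
62$). At a floor of 20 instead, 6–9-column chance alignments between
unrelated hydrophobic peptides reach 50% identity at a rate of roughly one
pair in nine, and the network stops separating families; at 60 we measured
no spurious edge in 500 unrelated pairs while related family pairs score in
the hundreds. Components of size ≥2 are numbered by descending member count
(ties by smallest member id); size-1 components are singletons.

## MSA, logos, cleavage transfer

The progressive aligner builds a UPGMA guide tree from pairwise
global-identity distances and merges profiles with sum-of-pairs column
scoring under the same matrix and gap model as the pairwise search — native
rather than shelling out to an external aligner, so the pipeline is
self-contained and its tie-breaks testable. For two sequences it reduces
exactly to the pairwise global alignment. Logo matrices report per-column
residue frequencies (gap-excluded) and information content
$IC = \log_2 20 - H$ with no small-sample correction (stated, so the bits
are comparable across groups of different sizes).

Cleavage sites transfer from a curated anchor table
(`cleavageSiteTable()`: bacteriocin, seed id, leader length; user-editable).
The anchor residue maps to its alignment column; each member's site is the
count of its residues in columns up to that column, so members gapped at
the site inherit the nearest preceding residue. Groups without a
characterized member get no prediction. The table bundled with the package
belongs to the synthetic seed set (below); with real seeds, supply leader
lengths from the primary literature.

## The synthetic data generator

`generateGenome()` emits single-contig annotated genomes: background genes
(random proteins of 180–420 aa, typical bacterial CDS sizes and safely
above the precursor bounds), implanted cluster cassettes built from seed
proteins mutated to a target identity and reverse-translated with uniform
codon choice (mining never reads codon bias), intergenic spacers of 20–200
nt, and decoy cassettes missing one required role. Architectures follow the
observed range: 1–3 precursor copies, 1–3 transporters, optional
Yip1/transposase/peptidase. Ground truth (coordinates, roles, realized
identities) goes in a manifest; in `unannotated` mode the precursor CDS is
omitted from the GFF3 so the ORF scanner has to find it.

Two deliberate generator choices:

- **Initiator handling.** Every emitted CDS starts with an in-frame stop
  guard followed by ATG, and gene products always begin with M. The
  bacterial genetic code folds every initiator codon to M on translation,
  so any other first residue could never round-trip; the guard stop pins
  the ORF scanner to the exact annotated start, making coordinate-exact
  recovery a testable contract rather than a coincidence of spacer content.
- **Nested divergence ladders.** `mutateToIdentity()` mutates `k =
  round(L(1-t/100))` positions, replacements drawn by BLOSUM
  exchangeability ($w \propto 2^{s/2}$). Two *independent* 60%-identity
  mutants of one seed are only ~36–45% identical to each other — below any
  family threshold — so a simulated family built that way could never
  co-cluster at 50%. With a shared `mutation_order`, the member at target
  $t$ mutates the first $k(t)$ positions of one fixed permutation with
  deterministic per-position replacements, emulating divergence along a
  lineage: members at $t_1 \ge t_2$ are exactly $100-(k_2-k_1)/L\cdot100$%
  identical. The benchmark set (`simulateBenchmarkSet()`) uses a nested
  ladder at 60–90% for five implants plus one independent 40% outlier that
  the network must leave apart.

What the generator does *not* emulate: multi-contig assemblies, real codon
usage and GC content, operon structure and promoters, insertion/deletion
divergence (substitution-only by default), annotation errors beyond the
premature-stop case, and real intergenic sequence composition. Passing the
recovery suite therefore shows the pipeline's logic is correct under
controlled divergence — not that its thresholds are optimal for any
particular real genome collection.

## The bundled seed set is synthetic

The package ships `seeds_synthetic.faa` / `seed_roles_synthetic.tsv`:
stand-ins for the 19 characterized circular bacteriocins (13 subgroup i, 6
subgroup ii), each with precursor, transporter and SpoIIM entries plus
accessory families. They are *constructed* sequences carrying the documented
properties — family structure matching the published similarity groups (the
six subgroup ii precursors mutually ≥50% identical; two bacteriocins with
identical mature peptides; three singleton families), cationic vs
neutral/hydrophobic cores, leaders of 2–48 aa with the subgroup ii leaders
ending in Asn — not database copies. All fixture tests state facts about
this synthetic set. For production mining, load real sequences with
`readSeedSet()`; every downstream stage is seed-set-agnostic.

## Problem sizes and determinism

The validation suites run at fixed sizes chosen to exercise each property
thoroughly on one CPU: 1,000 random pairs for aligner oracle equivalence
(lengths ≤6, plus 200 pairs against a full-enumeration brute force at
lengths ≤4), 500 peptides for the pI grid-scan comparison (within 1e−3 pH),
200 random graphs for the component/union-find equivalence, 100 random
6-taxon additive matrices for NJ recovery, and a 20-genome benchmark
simulation (6 complete clusters, 4 decoys, 10 negatives). All randomness
flows from explicit seeds; identical configuration gives byte-identical
outputs, which the suite asserts.

## Known limitations

- The verdict requires precursor homology to the seed set; a cluster whose
  precursor family is entirely novel surfaces only through its reported
  heuristic candidates, not as a `pass`.
- NJ on alignment distances replaces maximum-likelihood inference; the tree
  is a grouping visual, not a substitution-model estimate, and is unrooted.
- Identity near the 50% cutoff is sensitive to the identity denominator
  convention; ours (all aligned columns) is stated and fixed, but other
  tools' group counts may differ by a member or two near the boundary.
- Immunity genes are not detected (no characterized seed sequences to
  search with).
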
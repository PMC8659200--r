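# cycloMiner

Transporter-guided genome mining for head-to-tail cyclized (circular)
bacteriocins — ribosomally synthesized antimicrobial peptides whose N- and
C-termini are joined by an amide bond after leader cleavage. Their
biosynthetic gene clusters reliably encode at least a precursor peptide, one
or more ABC-transporter components, and a SpoIIM (DUF95) membrane protein.
Because the short precursors are poorly annotated, cycloMiner searches
genomes with the *transporter* proteins of characterized circular
bacteriocins and then screens each hit's genome neighborhood with the
three-gene co-occurrence filter. It is written for bacteriocin researchers
and RiPP genome miners who want the whole strategy — search, screening,
peptide physicochemistry, network grouping, logos, cleavage transfer,
phylogeny — as reproducible, tested R functions on local genomes, with no
web services involved.

## What it computes

- **Search**: Smith–Waterman local alignment (BLOSUM62, affine gaps
  `11 + (L−1)·1`) of transporter seeds against the genome proteome, with
  explicit identity/coverage/raw-score thresholds in place of E-values.
- **Cluster screening**: a window of *k* genes (default 10) around each
  transporter hit; role annotation of every window protein against the seed
  set; six-frame scanning for unannotated small ORFs (25–150 aa); verdict
  `pass` iff precursor ∧ SpoIIM ∧ transporter. Yip1, transposase and
  peptidase genes are reported as flags.
- **Physicochemistry**: Kyte–Doolittle GRAVY; Henderson–Hasselbalch net
  charge and bisection isoelectric point (EMBOSS pKa set), in linear or
  cyclic mode (the head-to-tail bond consumes both termini); subgroup i
  (cationic, cyclic charge ≥ +2) vs subgroup ii (neutral, GRAVY ≥ 0)
  classification.
- **Sequence similarity network**: all-by-all local alignment of unique
  precursors, edges at ≥50% identity and a raw-score floor of 60 (the
  peptide-scale analog of an E-value 1e−5 pre-filter); connected components
  as size-ranked groups plus singletons.
- **Group summaries**: native progressive MSA (UPGMA guide tree,
  profile–profile alignment), sequence-logo matrices (information content in
  bits), leader-cleavage-site transfer from characterized anchors.
- **Phylogeny**: neighbor-joining on global-alignment distances, Newick +
  leaf-annotation export.
- **Synthetic genomes**: a generator that implants ground-truthed clusters
  and decoys at controlled identity so every stage is testable offline.

The bundled seed set is a **synthetic stand-in** for the 19 characterized
circular bacteriocins (13 cationic subgroup i, 6 neutral/hydrophobic
subgroup ii), constructed to carry their documented family structure and
physicochemistry; swap in real sequences with `readSeedSet()` for production
mining. See `vignettes/transporter-guided-mining.Rmd` for the methods and
design decisions.

## Worked example

Simulate one genome carrying a cluster diverged to ~70% identity from the
enterocin AS-48 seed family, then mine it:

```r
library(cycloMiner)

cfg <- simConfig(seed = 42, genome_id = "demo",
                 clusters = list(clusterSpec("enterocin_AS-48",
                                             identity = 70)))
sim <- generateGenome(cfg)
res <- mineGenome(sim$genome)
bgc <- res$bgcs[[1]]
bgc
#> CandidateBGC demo:demo_c1 186-14727 [pass]
#>   15 gene(s); 18 precursor candidate(s)
precursors(bgc)[precursors(bgc)$support == "homology",
                c("length", "origin", "seed_identity_pct", "subgroup")]
#>  length        origin seed_identity_pct subgroup
#>     105 annotated_cds          71.84466        i
```

The window passed the co-occurrence filter (`pass`), and the implanted
precursor was recovered from the annotation at 71.8% identity to its seed —
the simulation's target was 70%. Of the 18 precursor candidates, 17 are
GRAVY-screened small ORFs kept only as low-confidence leads
(`support = "heuristic"`); the verdict rests on the homology-supported one.
Its physicochemical profile:

```r
physchemProfile(setNames(precursors(bgc)$sequence[1], "demo_precursor"))
#>              id      gravy net_charge_pH7 pI_linear subgroup
#>  demo_precursor -0.5971429       7.849394  10.93088        i
```

A cyclic net charge of +7.8 and a pI above 10 are the signature of a
subgroup i (cationic) circular bacteriocin. `runPipeline(runConfig(...))`
chains mining, profiling, the similarity network, logos/cleavage and the
tree over a genome collection and writes every table.

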
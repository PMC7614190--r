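# bivalentia

Peak-level analysis of bivalent chromatin and its regulators, as an R
package. It is aimed at epigenomics analysts who have peak calls and
per-sample counts in hand (ChIP-seq, CUT&RUN or CUT&Tag) and want a
tested, scriptable implementation of four bespoke downstream procedures
that are usually re-coded ad hoc:

1. **Bivalent-promoter classification** — a gene is *bivalent* when both
   H3K4me3 and H3K27me3 peaks overlap the window `[TSS − 2 kb, TSS + 2 kb)`;
   *k4_only*, *k27_only* and *unmarked* otherwise. The four states
   partition the gene universe.
2. **Reads-in-peaks quantification and knockout log fold change** —
   per-peak counts are normalized to reads per million mapped reads
   (RPM = count × 10⁶ / library size), summed per gene over the gene body
   extended 1 kb upstream of the TSS, and contrasted as
   `log2((KO + c) / (ctrl + c))` with pseudocount c = 0.5, replicates
   averaged on the RPM scale.
3. **Occupancy-redistribution analysis** — restrict to peaks with ≥ 1 RPM
   in at least one sample of both the factor (e.g. KMT2A) and H3K4me3
   data; call each covered peak *increased* (Δ ≥ 1 RPM), *reduced*
   (Δ ≤ −1 RPM) or *unchanged* where Δ is the knockout-minus-control
   condition-mean RPM; roll calls up to genes via TSS windows; summarize
   each group's bivalent composition and companion-mark shifts.
4. **FACS-sort CRISPR screen ranking** — sgRNA reads are counted by exact
   spacer match after constant-prefix trimming (multi-matching reads
   discarded), guides scored by the sorted-vs-unsorted RPM log2 ratio,
   and genes ranked by the RSA statistic: for a gene with k guides at
   ascending ranks r₁ < … < r_k among N ranked guides,

   p(G) = min over j of P(X ≥ j), X ~ Hypergeometric(N, k, r_j),

   then tiered (*high* p < 10⁻⁵, *moderate* 10⁻⁵ ≤ p < 10⁻⁴, *low*
   10⁻⁴ ≤ p < 10⁻³) with a gate of ≥ 4 enriched guides (score ≥ 1, i.e.
   2-fold), and dual-screen hits intersected by the worse p-value.

A set-level integration module (Benjamini–Hochberg step-up FDR, strict
differential-expression thresholds q < 0.05 and |log2FC| > 1, venn-region
summaries, bivalent fractions, gene-effect co-dependency by Pearson
correlation) and a synthetic-data generator with planted ground truth
(gene classes, a planted factor redistribution, planted screen
repressors) complete the pipeline, so every stage is testable without any
external download. Coordinates are 0-based half-open (BED convention)
throughout.

## Worked example

```r
library(bivalentia)
g    <- make_genome(n_genes = 500, seed = 11)
ctrl <- simulate_mark_data(g$genes, g$truth, "control",  depth = 1e6, seed = 12)
ko   <- simulate_mark_data(g$genes, g$truth, "knockout", depth = 1e6, seed = 13)

calls <- classify_bivalency(g$genes, ctrl$peaks$H3K4me3, ctrl$peaks$H3K27me3)
table(calls$state)
#> bivalent k27_only  k4_only unmarked
#>      155      102      206       37

covered <- filter_covered_peaks(cbind(ctrl$rpm$KMT2A, ko$rpm$KMT2A),
                                cbind(ctrl$rpm$H3K4me3, ko$rpm$H3K4me3))
changes <- classify_peak_changes(ctrl$rpm$KMT2A, ko$rpm$KMT2A, covered)
gcat    <- rollup_to_genes(changes, g$genes, ctrl$universe$KMT2A)
group_composition(gcat, calls)
#>         group n_genes n_bivalent fraction_bivalent
#> 1   increased      96         66         0.6875000
#> 2 not_covered     121          0         0.0000000
#> 3     reduced     232         39         0.1681034
#> 4   unchanged      51         50         0.9803922

screen <- simulate_screen(g$truth, depth = 5e6, seed = 14)
scores <- guide_enrichment(screen$counts)
hits   <- tier_hits(rsa_rank(scores, screen$library), scores, screen$library)
head(hits[hits$tier != "none", ], 3)
#>   gene_id n_guides            p      logp n_enriched tier
#> 1   g0209       10 3.041717e-14 -13.51688          9 high
#> 2   g0258       10 3.751298e-14 -13.42582          9 high
#> 3   g0409       10 4.302551e-14 -13.36627          9 high
```

Reading the output: the classifier recovers the designed chromatin
classes (155 bivalent genes out of 500); the redistribution analysis
finds an *increased* group that is 69% bivalent — the planted gain genes
are drawn 63% from the bivalent class, plus a few noise-flipped stable
genes (see the methods vignette on why the ±1 RPM threshold is noisy at
this depth); and the screen recovers all 20 planted repressors at tier
`high` with 8–9 of 10 guides enriched each.

The same stages are scriptable from the shell via `exec/bivalentia`
(`simulate-genome`, `simulate-marks`, `bivalency`, `quantify`, `lfc`,
`redistribute`, `screen-count`, `screen-rank`, `de-sets`, `overlap`,
`bivalent-fraction`, `codep`, `simulate-screen`, `simulate-effects`); all
stages are byte-deterministic given `--seed`.

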
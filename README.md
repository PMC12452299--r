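# xresponse

Chromosome-level analysis of transcriptional responses to loss of the
XIST/Xist long noncoding RNA.

XIST initiates X-chromosome inactivation (XCI), the silencing of one X in
female mammalian cells. Deleting or knocking it down raises a quantitative
question: does the X chromosome show a *distinct* transcriptional response
compared with autosomes, and does that response depend on cell state?
`xresponse` is for computational biologists comparing bulk RNA-seq datasets
of XIST/Xist-deficient vs control cells. It implements the full comparative
pipeline:

- **Per-chromosome DEG percentages and rankings** — `%DEG(c) = 100 ·
  n_DEG(c) / n_genes(c)`, ranked in descending order (X among 23 human / 20
  mouse chromosomes), with pooled two-proportion Z tests
  `z = (p̂₁ − p̂₂)/√(p̂(1−p̂)(1/n₁+1/n₂))` of the X against pooled autosomes
  and of the top-ranked chromosome against the rest.
- **Fold-change distribution shifts** — exact two-sample Kolmogorov–Smirnov
  D with asymptotic two-sided p, comparing X vs autosomes, a
  gene-count-matched control autosome (chr9 human / chr10 mouse) vs the
  other autosomes, and X vs that control.
- **Multi-dataset DEG overlap** — exclusive (UpSet-style) membership counts
  and plain intersections, per direction.
- **Allele-specific expression** — allelic ratio
  `AR = min(refCount, altCount)/(refCount + altCount)` per SNP (≥ 10 reads),
  read-count-weighted per-gene aggregation, `ΔAR = AR_KD − AR_CTRL` per
  knockdown clone, concordance classification, and an escape-vs-inactive
  2×2 with sample odds ratio `ad/bc`, exact Fisher p, Shapiro–Wilk and
  Mann–Whitney tests.
- **Sliding-window density correlations** — 1 Mbp windows every 250 kbp
  along the X; Pearson correlations of X-linked DEG density with gene, SINE
  and LINE density; first-order partial correlation
  `r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²))` of DEG density with
  SINE density controlling for gene density; cross-dataset correlations of
  DEG tracks on a shared grid.
- **A synthetic-data generator** with known ground truth (clustered gene
  positions, copula-coupled SINE/LINE densities, negative-binomial counts,
  binomial allelic counts) plus a minimal moderated NB Wald DE test, so the
  whole pipeline is testable without downloading anything.

Real data enter as DESeq2-style results tables, raw count matrices, GTF/BED
gene annotations, RepeatMasker `.out`/BED repeat tracks, per-SNP allele
count tables and XCI status tables (all tab-separated). See the methods
vignette (`vignettes/xist-loss-response.Rmd`) for the statistical choices
and generator design.

## Worked example

```r
library(xresponse)

cfg <- simulation_config(scenario = "stem")       # pluripotent-like scenario
sim <- simulate_dataset(cfg, seed = 1, alleles = FALSE)
de  <- de_test(sim$counts)                        # minimal NB Wald test
run <- run_dataset(de = de, ann = sim$annotation,
                   repeats = sim$repeats, label = "stem-demo")
print(run)
```

```
xresponse_run 'stem-demo': 23 DEGs (22 up, 1 down) across 23 chromosomes
  X: 8.20% up (rank 1/23), 0.39% down (rank 1/23); control chromosome chr13
  KS X vs autosomes: D = 0.1456, p = 6.74e-05 [right]
```

The stem scenario plants a log2 fold change of 1 in 15% of X-linked genes:
the X ranks 1st among the 23 chromosomes for upregulated DEGs (8.2% of its
256 genes vs ≤ 0.5% on any autosome), the fold-change distribution of
X-linked genes is significantly right-shifted relative to autosomes, and
the single downregulated DEG is the simulated knockdown target XIST itself.
The density stage recovers the planted positional structure:

```r
run$density$correlations
```

```
             pair    kind controlled_for       r         p   n
 deg_all vs genes pearson           <NA>  0.4828 1.427e-37 621
  deg_all vs sine pearson           <NA>  0.2078 1.731e-07 621
  deg_all vs line pearson           <NA> -0.2610 3.949e-11 621
  deg_all vs sine partial          genes -0.1191 2.966e-03 621
```

DEG density follows gene density (r = 0.48 over 621 windows), correlates
positively with SINE and negatively with LINE density — and the DEG–SINE
correlation collapses once gene density is controlled for, exactly the
signature of a SINE association driven by gene-rich regions.

A thin command-line wrapper over the same functions ships at
`inst/scripts/xresponse` (subcommands `simulate`, `de`, `chrom-response`,
`overlap`, `allelic`, `density`, `run`).

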
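# dosegrade

Dose-graded transcriptome analysis of B-cells expressing wild-type or
T58-mutant MYC.

## What this package is for

When a tetracycline-regulated MYC transgene is titrated across seven
doxycycline doses (0–1000 ng/mL) in three genotypes — wild-type MYC and
the lymphoma-associated T58A and T58I substitutions — the resulting
RNA-seq data ask four dose-graded questions:

1. which genes respond to progressively increasing MYC levels, and which
   respond *differently* under a T58 substitution;
2. how the responding genes organize into expression-profile clusters,
   and what characterizes each cluster (direction, expression level,
   biotype, gene length, E-box proximity);
3. whether canonical E-boxes (CACGTG, the high-affinity MYC/MAX motif)
   lie unusually close to the transcription start sites of responsive
   genes;
4. whether gene sets are systematically more sensitive to MYC dose under
   T58A than under T58I.

`dosegrade` implements that analysis end-to-end for anyone with a
gene-level count matrix and a genotype × dose × replicate design:
tidyverse-style functions that take data frames and return tibbles, plus
a one-call pipeline. A synthetic-data generator with known ground truth
(NB counts around genotype-specific Hill dose-response curves, a genome
with E-boxes planted at controlled TSS distances, truth-linked gene-set
collections) makes the whole pipeline testable without any download.

The statistical core:

* **Dose-response DE** — per-gene NB factorial GLM (one mean per
  genotype × dose cell, log library-size offsets), Cox–Reid adjusted
  profile-likelihood dispersions moderated toward a mean–dispersion
  trend, quasi-likelihood F-tests for (i) any WT dose effect and (ii) a
  mutant dose profile differing from WT beyond an intercept shift, BH
  q-values per family, and the selection rule *q* < 0.01 with a maximal
  fitted-mean fold change ≥ 2.
* **Profile clustering** — Ward (`ward.D2`) hierarchical clustering of
  replicate-averaged log2 RPKM profiles cut at *k* = 12, with a
  characterization table combining chi-squared enrichments and
  1000-fold resampling tests against the non-regulated background.
* **E-box proximity** — exact CACGTG scanning (palindrome-aware), minimal
  unsigned TSS-to-motif-midpoint distances, ±1 kb proximity flags,
  nearest-gene annotation per motif.
* **Set enrichment** — Venn decomposition of the three selection flags
  into regions A–G, signed Fisher over/under-representation heatmaps
  against clusters, GMT over-representation analysis, and overlap tests
  against external gene lists through an ortholog map.
* **Sensitivity GSEA** — the dose-sensitivity score
  s = FC(25/0) / FC(600/300) per genotype, the preranked metric
  log2(s_T58A / s_T58I), and a from-scratch preranked GSEA (running sum,
  gene-label permutation null, NES, BH FDR, leading edge) with the
  selection rule padj ≤ 0.05 and |NES| ≥ 1.7.

## Worked example

```r
library(dosegrade)
summary <- run_pipeline(outdir = "demo_run", seed = 7)
str(summary$stage_counts)
```

```
 $ simulate: n_genes 800, n_samples 63, n_regulated_truth 240,
             n_differential_truth 120
 $ de      : n_retained 800, n_selected 240, n_regulated_wt 226,
             n_diff_t58a 31, n_diff_t58i 25
 $ ebox    : n_hits 467, n_genes_with_ebox_1kb 239
 $ cluster : k 12, n_clustered 240, size_range 7 33
 $ sets    : A 193, B 7, C 4, D 15, E 12, F 3, G 6
 $ ora     : n_sets 6, n_significant 3
 $ gsea    : n_sets 6, n_enriched 3
```

The simulation planted 240 WT-regulated and 120 mutant-differential genes
among 800; the DE stage calls 226 of the WT-regulated genes and 31/25
mutant-differential genes (the per-gene interaction test is deliberately
conservative — the set-level analyses below are where moderate
differential effects become visible). All 467 genome E-box hits are
planted motifs, 239 genes carry one within 1 kb of their TSS. The three
truth-enriched gene sets — and none of the three uniform control sets —
are detected both by over-representation analysis of the
mutant-differential genes and by the sensitivity-ranked GSEA:

```r
readr::read_tsv("demo_run/gsea_results.tsv")
#>   set             size     es   nes  p_perm   padj significant
#> 1 enriched_t58a_1   25  0.654  2.11 0.00515 0.0114        TRUE
#> 2 enriched_t58a_2   25  0.732  2.49 0.00568 0.0114        TRUE
#> 3 enriched_t58a_3   25  0.756  2.48 0.00532 0.0114        TRUE
#> 4 control_1         25 -0.539 -1.54 0.04720 0.0639       FALSE
#> 5 control_2         25 -0.439 -1.29 0.14159 0.1416       FALSE
#> 6 control_3         25 -0.502 -1.43 0.05329 0.0639       FALSE
```

Every output lands in `demo_run/` as plain TSV/FASTA/BED/GMT plus a
`run_summary.json` with an md5 manifest; re-running with the same seed
reproduces every file byte-for-byte. Individual stages are ordinary
functions (`fit_dose_response()`, `hierarchical_cluster()`,
`scan_motif()`, `venn_decompose()`, `gsea_preranked()`, ...) that accept
tibbles, so real count matrices and annotations drop in directly; `tidy()`
and `glance()` extract per-gene results and one-row summaries from the DE
fit, and `autoplot()` / `plot_*()` helpers cover the standard figures.

See the vignette (`vignettes/dose-graded-myc-analysis.Rmd`) for the model
details, the generator's assumptions, and the package's design decisions.

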
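---
title: "Dose-graded transcriptome analysis of wild-type and mutant MYC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-graded transcriptome analysis of wild-type and mutant MYC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosegrade)
```

## The experimental design this package models

A tetracycline-regulated MYC transgene is titrated in primary B-cells with
seven doxycycline doses (0, 25, 50, 100, 300, 600 and 1000 ng/mL) across
three genotypes — wild-type MYC and the lymphoma-associated T58A and T58I
substitutions — with replicated bulk RNA-seq at each genotype × dose
condition. The scientific questions are dose-graded: which genes respond to
progressively increasing MYC levels, which respond *differently* when the
protein carries a T58 substitution, how the responding genes organize into
expression-profile clusters, whether high-affinity canonical E-boxes
(CACGTG) sit close to the transcription start sites (TSS) of responsive
genes, and whether gene sets are systematically more sensitive to MYC dose
under T58A than under T58I.

`dosegrade` implements that full analysis as composable, data-frame-first
functions plus a one-call pipeline (`run_pipeline()`), together with a
synthetic-data generator so that every stage can be exercised and verified
without access to sequencing data.

## The dose-response differential-expression model

Counts $y_{gs}$ for gene $g$ in sample $s$ are modelled as negative
binomial with gene-wise dispersion $\phi_g$ and mean
$\mu_{gs} = \lambda_s \, m_{g,c(s)}$, where $\lambda_s$ is the library-size
offset (column sums by default) and $m_{g,c}$ is one free mean per
genotype × dose cell $c$ — a saturated 21-cell factorial, fitted by Fisher
scoring. Two families of reduced models yield the tests:

* **Dose effect in WT** — WT means collapsed to a single level across the
  seven doses (6 df). Only WT samples contribute to the deviance
  difference.
* **Differential response for each mutant** — the mutant's dose profile is
  constrained to the WT profile up to one intercept shift
  ($\log m_{M,d} = \log m_{WT,d} + c$, 6 df). A mutant that merely scales
  all doses equally is *not* differential; only a changed profile shape is.
  This model is fitted by blockwise Fisher scoring (dose means given the
  shift; the shift given the means), which decreases the deviance at every
  step; iteration stops at a relative deviance change below $10^{-8}$ or
  100 iterations.

Dose is treated as a 7-level factor, not a continuous covariate: it
imposes no curve shape on real data and matches the condition-wise way the
results are reported downstream (profile clusters, condition means).

**Dispersion.** Gene-wise $\phi_g$ maximizes the Cox–Reid adjusted profile
likelihood on a dispersion grid (cell means re-fitted at each candidate,
quadratic interpolation at the optimum), then is moderated toward a
lowess mean–dispersion trend on the log scale with shrinkage weight 0.3
(configurable). With one replicate everywhere the gene-wise estimator is
undefined and `estimate_dispersion()` asks for
`common_dispersion = TRUE`.

**Testing.** The GLMs used for testing are fitted with the *trended*
dispersion; each gene's departure from the trend is then carried by its
quasi-dispersion scale rather than absorbed into $\phi_g$, which is what
keeps the F-test's extreme tail calibrated (feeding the gene-wise
estimate into the fit deflates the denominator and produces spuriously
tiny p-values). Each family uses a quasi-likelihood F statistic
$F = (\Delta\text{dev}/\Delta df) / s^2_g$, where $s^2_g$ is the gene's
residual deviance scale squeezed toward its mean–variance trend by
empirical Bayes (`limma::squeezeVar`); the reference distribution is
$F(\Delta df,\ df_{res} + df_{prior})$. Benjamini–Hochberg adjustment is
applied **within each family separately** — the natural choice when gene
counts are reported per family, and the conservative one when the families
have very different signal densities. A gene is *selected* in a family
when $q < 0.01$ and the largest fitted-mean ratio over the family's
condition pairs is at least 2-fold. Fold changes are computed on fitted
cell means floored at 0.125 CPM — fitted rather than observed means
because the factorial fit is the quantity the test is about, and the floor
keeps fold changes finite for cells estimated at zero.

Unit tests cross-check this machinery against edgeR's `glmQLF` workflow on
identical data (rank correlation of p-values > 0.9); exact numerical
equality with any specific external implementation is not a goal.

## Profile clustering and the characterization battery

Selected genes (the union of the three families) are summarized as
replicate-averaged $\log_2(\text{RPKM} + 1)$ profiles over the 21
genotype-major, dose-ascending conditions, clustered with Euclidean
distances and Ward's method (`ward.D2`, the variance-minimizing form on
unsquared distances), and cut to $k = 12$ flat clusters by default.
Cluster labels follow `cutree`'s order of first appearance and carry no
meaning beyond identity — the partition, not the numbering, is the result
(shuffling gene order relabels but never repartitions).

`build_cluster_table()` computes, per cluster: size; percent up/down
(replicate-mean RPKM at 1000 ng/mL versus 0 ng/mL, strict inequalities,
ties a third "unchanged" category; classified on the reference genotype by
default); the overall pattern (direction of > 50 % of genes); median RPKM;
percent non-coding and percent with an E-box within 1 kb of the TSS, each
with a 2×2 chi-squared test (continuity-corrected, Fisher's exact when an
expected cell drops below 1) against the non-regulated background; median
gene length and median minimal TSS–E-box distance, each with a resampling
test: 1000 draws of cluster-size subsets (without replacement) from the
background, two-sided empirical p-value
$2\min(r_{low}+1, r_{high}+1)/(B+1)$, capped at 1 — the $+1$ estimator
never reports zero. Within each statistic the p-values are BH-adjusted
across the clusters; significance is called at adjusted $p < 0.05$
(categorical) and $< 0.02$ (resampling).

## E-box proximity

`scan_motif()` reports every exact, case-insensitive occurrence of CACGTG
on both strands (N never matches). Because the motif is its own reverse
complement, forward and reverse alignments coincide position-for-position:
the default `"positions"` mode counts each genomic start once (flagged
palindromic), while `"alignments"` mode doubles the records to mirror the
output convention of an exhaustive aligner. Distances are measured from
the strand-aware gene 5′ end (one TSS per gene) to the motif midpoint
(start + 3 for a hexamer), unsigned — upstream and downstream count
equally — and the proximity flag uses an inclusive 1000 bp window. A gene
on a chromosome without any hit gets a missing distance and a `FALSE`
flag. The scanner's contract is exactness: tests compare it to a naive
sliding-window oracle on random sequences and to planted motif positions
on synthetic genomes.

## Venn decomposition and enrichment

The three selection flags define seven disjoint Venn regions A–G (A: WT
only; B/C: one mutant only; D/E: WT plus one mutant; F: both mutants
without WT; G: all three). `sets_by_clusters_heatmap()` runs both
one-tailed Fisher tests for every region × cluster cell, BH-adjusts across
all cells and tails jointly, and reports signed $-\log_{10}$ adjusted
p-values (positive = over-represented). `ora_gmt()` is a standard
hypergeometric over-representation test against a GMT collection with BH
adjustment (significant at FDR ≤ 0.1), and `external_overlap()` compares a
gene set against a published list, optionally translated through a
two-column ortholog map (exact lookup, unmapped entries dropped and
counted). Every Fisher-type test in the package uses the same universe:
the genes passing the expression filter. Odds ratios are sample odds
ratios; two-sided p-values follow the minimum-likelihood convention of
`fisher.test`.

## The sensitivity statistic and preranked GSEA

For each genotype, gene-level dose sensitivity is the ratio of the
low-dose fold change to the high-dose fold change on replicate-mean RPKM
(pseudocount 0.125): $s = \mathrm{FC}_{25/0} / \mathrm{FC}_{600/300}$. A
gene already responding between 0 and 25 ng/mL has $s \gg 1$; a gene that
only moves at high dose has $s < 1$. The preranked metric is
$\log_2(s_{T58A}/s_{T58I})$ — the log transform is order-preserving (so
the ranking is identical to the raw ratio) and makes the running-sum
weights symmetric in the two mutants.

`gsea_preranked()` is a from-scratch implementation: genes sorted by
metric (ties broken by gene id — documented because the score depends on
order within ties), hits add $|m|^p/N_R$ (weight $p = 1$), misses subtract
$1/(N - n)$, and the enrichment score is the signed maximum-magnitude
running-sum deviation (a tie between tails resolves to the positive one).
The null is gene-label permutation: random same-size sets; NES divides ES
by the mean magnitude of same-sign null scores; $p = (r+1)/(n_{same}+1)$;
BH across sets. The leading edge is the members at or before the score's
extremum (after it for negative scores). Sets are selected at adjusted
$p \le 0.05$ **and** $|NES| \ge 1.7$, both bounds inclusive. Tests pin the
score to a literal position-by-position running sum (to $10^{-12}$,
exhaustively over all 3-subsets of a 7-gene list) and to
`fgsea::calcGseaStat` as an independent implementation.

## What the synthetic-data generator emulates

`simulate_experiment()` draws NB counts around gene-wise monotone Hill
dose-response curves,
$\mathrm{CPM}(d) = e^{b} \cdot 2^{a \, h(d)}$ with
$h(d) = d^s/(d^s + \mathrm{EC50}^s)$, under the full 3 genotypes × 7 doses
× 3 replicates design. The defaults are the package's study conditions,
chosen once:

* **Baseline expression** $b \sim U(2.5, 6.5)$ on the natural-log CPM
  scale (≈ 12–665 CPM): the reliably quantified part of a bulk
  transcriptome. The expression filter's boundary behaviour is exercised
  by dedicated tests rather than by the default generator.
* **Amplitude** $|a| \sim U(1, 3)$ log2 units, sign = direction (up/down
  equally likely); 30 % of genes regulated.
* **Hill slope 4** — a steep, switch-like induction such as a
  cooperatively activated tet-on transgene produces. With a shallow curve
  most of the labelled amplitude is never realized inside the dose grid,
  which would make the generator's "amplitude" label systematically
  overstate the planted effect; the steep curve makes the label honest
  (the realized span is ≈ the labelled amplitude) and places interior
  doses on both sides of the transition.
* **EC50 by genotype**: T58A 25 < WT 100 < T58I 450 ng/mL, encoding the
  qualitative sensitivity ordering (T58A responds already at the lowest
  dose; T58I needs high dose). 15 % of genes are mutant-differential:
  70 % "shift" genes (regulated everywhere, the mutant's own EC50 and a
  scaled amplitude — ×1.5 for T58A, ×0.6 for T58I) and 30 % mutant-only
  responders (flat in WT).
* **Dispersion** gene-wise from Gamma(2, 20) (mean 0.1, long right tail),
  the magnitude typical of replicated bulk RNA-seq; **library sizes**
  log-uniform on 0.8–1.5 million reads so normalization is always
  exercised; 20 % non-coding biotypes; gene lengths log-normal
  (meanlog 8, sdlog 0.8 bp).
* **Genome**: one chromosome, one 10 kb window per gene, TSS at the window
  centre, random strand. E-boxes are planted at controlled TSS distances
  (up-regulated genes mostly 50–800 bp; others mostly far or absent) and
  the background is rejection-resampled until it contains no accidental
  CACGTG, so the planted positions are the complete truth. Planted
  distances stay below half the window spacing so a gene's own motif is
  always its nearest.
* **Gene sets**: enriched sets draw 80 % of their 25 members from the
  "more sensitive in T58A, up-regulated" truth category, the rest (and the
  control sets) uniformly. Directional coherence matters: a set whose
  members sit in both tails of the rank metric is invisible to any
  running-sum statistic, as it would be for a real pathway scored by a
  real GSEA.

All randomness flows from one seed through deterministically derived
per-stream sub-seeds; identical configurations give byte-identical output
files.

What the generator does **not** emulate: batch effects, isoform-level
variation, GC/length biases in counting, correlated genes, composition
shifts beyond those induced by the planted regulation itself, and
multi-chromosome genomes. Passing tests therefore demonstrate correctness
of the statistical machinery under a clean NB world, not robustness to
every artefact of real sequencing data.

## Numerical and design choices

* Library-size normalization is plain column-sum scaling. When a large
  fraction of the transcriptome responds in one direction, column sums
  absorb part of the signal (a known composition effect); the package
  accepts explicit `library_sizes` everywhere, so externally computed
  size factors can be injected. No TMM-style correction is built in.
* Fisher scoring for cell means caps steps at ±5 on the log scale and
  converges to $|U| < 10^{-10}(I+1)$; all-zero cells give a zero fitted
  mean and contribute zero deviance.
* Deviance differences are floored at zero (the reduced model is nested).
* Pseudocounts: 0.125 CPM for fold changes and the sensitivity statistic;
  1.0 for the clustering log transform (profiles are on a coarser scale
  and a larger floor suppresses low-expression noise).
* `pf` with an infinite prior df (limma's moderated scale on clean data)
  degrades gracefully to the chi-squared reference.
* Problem sizes used by the test-suite and the acceptance script — 2000
  genes for calibration/recovery, 500-permutation GSEA nulls, 20
  end-to-end runs of the 800-gene default pipeline — were chosen as the
  smallest sizes at which the binomial/Monte-Carlo noise of the measured
  rates is small against their acceptance margins.

## Limitations

The per-gene mutant-differential test is intrinsically less powerful than
the WT dose test: an intercept-free profile-shape difference spreads over
6 df and is shared between both genotypes' samples, so moderate EC50
shifts are often invisible at the gene level even when set-level analyses
(ORA on the differential flags, sensitivity GSEA) detect them clearly.
That mirrors the analytic structure of the original design rather than an
implementation defect. Cluster numbering is arbitrary; only partitions are
comparable across runs. The resampling tests condition on the observed
background and are exact only in the Monte-Carlo sense.
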
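---
title: "Methods and modeling choices in rrmp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in rrmp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `rrmp`, the assumptions it makes,
the parameters that matter, and the numerical and design choices that were
genuinely open. It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## The physical process being modeled

Reduced representative methylome profiling couples two chemistries:

1. **Conversion.** An enzymatic (EM-seq-style) treatment converts
   unmethylated cytosine to thymine while 5mC/5hmC are protected. Each
   sequenced strand of each library molecule is converted independently.
2. **Depletion.** The converted library is digested with restriction
   enzymes whose recognition sites contain only A and T: MseI (`TTAA`)
   for the 1-cut panel; MseI, MluCI (`AATT`), SspI (`AATATT`) and PsiI
   (`TTATAA`) for the 4-cut panel. Conversion turns most cytosines of
   AT-rich fragments into thymines, creating sites; molecules containing
   any complete site are cut and lost during re-amplification. CpG-dense
   fragments keep their G's (conversion never touches G on the read
   strand), so AT-only sites stay rare there and those molecules survive.

`rrmp` models only the sequence-level consequences of these steps.
Adapters, PCR, pooling amounts and enzyme kinetics are intentionally
absent: digestion is complete (a molecule with a site is always lost —
the wet protocol repeats digestion/amplification precisely to approach
this limit), and a site must lie entirely within the insert to cut,
since the adapter sequence context is not modeled.

## Coordinate and data conventions

* Containers are the Bioconductor stack: genomes are `DNAStringSet`,
  interval sets are `GRanges` (1-based, closed — the native convention of
  that stack), BED I/O converts at the file boundary via `rtracklayer`.
* A CpG unit is keyed by its Watson-strand C coordinate; Crick-strand
  evidence (the G one base to the right) is folded onto that key. One
  beta per unit: strand-symmetric methylation, the biological default;
  hemimethylation is not modeled.
* Methylation state is drawn **once per CpG unit per molecule**
  (`Bernoulli(beta)`), not per strand position: a library molecule derives
  from one strand of one original duplex.
* CH (non-CpG) methylation is not modeled; every retained non-CpG C in a
  converted molecule is therefore a conversion failure, which is exactly
  what the "more than 3 CHs" read filter (`filter_non_conversion`,
  `max_ch = 3`) assumes.
* Conversion and protection efficiencies default to 1.0 (ideal
  chemistry). Both are exposed in `conversion_params()` because real
  conversions are imperfect; sequencing error is out of scope (the real
  pipeline handles it in trimming/alignment).

## The synthetic genome

`simulate_genome()` emulates the one architectural fact RRMP exploits:
CpG islands are G+C-rich and CpG-dense, the background is AT-rich and
CpG-poor. A single chromosome alternates AT-rich spacers (G+C 0.25,
lengths 4–8 kb) with islands (G+C 0.65, lengths 0.8–1.5 kb, one forced
`CG` every ~12 bp — per-base sampling plus CpG seeding, not an island
detector, since real analyses use annotation files). One TSS sits at each
island midpoint with alternating strand; promoters are 1 kb upstream /
500 bp downstream of the TSS; shores are the 2 kb island flanks and
shelves the next 2 kb, truncated at gap midpoints so no base is assigned
twice. Ground-truth betas are Uniform(0, 0.2) inside islands and
Uniform(0.7, 1) outside — the canonical somatic pattern.

What this generator does **not** emulate: hg19-scale composition
heterogeneity (isochores, repeats), CpG-island methylation heterogeneity,
fragment-end sequence biases, and chromosome-scale structure. Tests that
pass on it demonstrate the mechanics and statistics of the method, not
performance on real genomes; absolute capture counts in particular are
not comparable to any published dataset.

Fragment lengths: `cfdna` mode draws Normal(170, 10) (the sharp
mono-nucleosomal plasma peak), `gdna` mode Normal(250, 80) (mechanical
shearing), both truncated at 30 bp.

## Digestion-side operations

* `scan_sites()` reports every exact occurrence (overlaps included) of
  every panel site; `N` never matches. All built-in sites are palindromic,
  so scanning the given strand suffices; custom non-palindromic enzymes
  are additionally scanned as their reverse complement.
* `converted_site_map()` gives the deterministic genome-level site track
  per strand. Two methylation rules are provided because a static track
  needs a consensus where molecules vary: `all_unmethylated` (maximal
  site set) and `threshold` (CpGs with beta ≥ 0.5 protected). Crick sites
  are reported in the Watson frame at the leftmost base under the site.
* `intersite_coverage_profile()` annotates every position between two
  consecutive same-strand sites with the gap length d (end of the
  upstream site to start of the downstream one) and averages retained
  depth per d bin. Gaps shorter than the fragment length can hold no
  retained molecule that covers them; depth rises toward the unfiltered
  expectation as d grows. On small island/background genomes the
  converted-space site spacing is 50–130 bp everywhere, which leaves no
  wide gaps — the package's tests therefore use a designed gap-sweep
  genome (C/G segments, which cannot form AT-only sites, separated by
  `TTAA` at controlled spacings) to measure this relationship cleanly.

## Capture, saturation and enrichment metrics

"Combined coverage" of an element is interpreted as the **sum** of
per-CpG depths over the element's CpGs, with ≥ 100 as the capture
criterion; a mean rule is available (`rule = "mean"`) since the phrase is
not self-defining. Downsampling is by cumulative base pairs, not read
count, and the molecule that crosses the target is included. The grid is
evaluated on nested prefixes of one seeded permutation, which makes
saturation curves exactly monotone rather than monotone in expectation.
Element read fractions use a ≥ 1 bp overlap rule and are intentionally
not mutually exclusive; with zero molecules they are undefined (`NA`),
never zero.

## Methylation statistics

* **Concordance** restricts to CpGs at or above a depth floor in both
  tracks and reports Pearson r plus the fraction with |Δβ| > 0.5 (a
  switched methylation state).
* **DMR calling.** Candidate regions are maximal runs of CpGs with
  inter-CpG gap ≤ 100 bp, split to ≤ 300 bp spans; a region is testable
  only if its pooled depth reaches 10× in every sample. The test is a
  two-sided Fisher exact test on pooled methylated/unmethylated counts of
  group A vs group B. Pooling across samples ignores between-sample
  variance — a known simplification; with few samples per group and
  moderate depths it is the exact, dependency-free choice, and the
  package's null-calibration test (binomial resampling at depth 100)
  shows the resulting p < 0.05 rate sits slightly below nominal
  (discreteness of the exact test), within [0.03, 0.07]. The Δβ
  thresholds are applied inclusively (≥); `delta_strict = TRUE` gives the
  strict reading, which the common printed form ("Δ beta > 0.5") leaves
  ambiguous.
* **Promoter one-vs-rest comparisons** use the same Fisher machinery on
  TSS ± 4 kb regions with Benjamini–Hochberg q values per cell across its
  tested regions (q ≤ 0.01, |Δβ| ≥ 0.5 by default).
* **Peak association.** For each cell's specifically hypomethylated
  regions (pooled beta < 0.10), the 2×2 table contrasts containment of
  the cell's **own** peaks versus the **other** cell's peaks, with a
  two-sided Fisher exact p per cell. Tabulating "contains own peak"
  against region specificity instead would read p = 1 precisely when
  methylation and chromatin co-locate perfectly, inverting the intended
  meaning — hence the own-vs-other contrast.

## The cfDNA classifier

`simulate_cohort()` generates the two-group study: a shared normal
profile (the genome's ground truth), per-sample inter-individual
variation `Beta(mu * k, (1 - mu) * k)` with concentration `k = 10`
(inter-individual sd ≈ 0.14 at mu = 0.5, a realistic scale for variable
CpGs), and observed counts binomial at Poisson(depth) coverage. Cancer
samples are shifted at `n_informative_cpgs` promoter CpGs by
`tumor_fraction × effect_delta` — the ctDNA mixture: at tumor fraction f,
a full-tumor effect Δ appears in plasma attenuated to fΔ.

The analysis chain mirrors standard practice: QC keeps autosomal CpGs
deeper than 100× in more than 80% of samples (both strictly "more
than"), then drops samples with more than 20% of kept sites below 100×;
features are CpGs within TSS ± 2 kb; classification is leave-one-out
ridge logistic regression with feature selection repeated inside every
fold.

Two defaults here required care, and both were set by measurement on the
package's own null invariant (a null cohort must score AUC ≈ 0.5):

* **Variance filtering is fold-safe by default.** The conventional single
  global feature set (across-sample variance ≥ 0.009 computed once on all
  samples) lets between-group differences count toward the variance
  threshold, so under the null it preferentially admits chance-separated
  CpGs — a real information leak that measurably inflates null AUC.
  `loo_classify(variance_in_fold = TRUE)` applies the 0.009 threshold to
  the training fold only; the global route remains available
  (`feature_prefilter(var_min = 0.009)` followed by
  `variance_in_fold = FALSE`) for mirroring published practice.
* **Selection is deliberately weak** (`n_features = 500` by default,
  ridge-regularized, balanced class weights). With ~60 samples, selecting
  a few dozen top-t CpGs per fold concentrates the model on
  chance-separated features and makes pooled leave-one-out scores
  unstable in both directions; a broad panel under ridge keeps null
  cohorts near AUC 0.5 while planted signal (tumor fraction 0.3, Δ = 0.5,
  depth 200, n = 60) is still recovered essentially perfectly. Balanced
  class weights correct the fold-composition artifact of leave-one-out
  (the held-out sample's class is under-represented in its own training
  fold, which otherwise biases every score against its true class).

AUC uses the rank (Mann–Whitney) formulation with ties counted 1/2; the
reported operating threshold is Youden's J on the pooled LOO scores,
configurable, since no standard threshold rule exists for tumor-score
cutoffs. Missing betas are imputed with training-fold feature means.

## Determinism and problem sizes

Every stochastic operation takes an explicit seed and is reproducible
byte-for-byte under it; pipeline stages derive child seeds from one
master seed. The shipped analyses use desk-scale problem sizes chosen to
keep the full test suite in minutes: genomes of 10–20 islands (~75–150
kb), libraries of 10³–4×10⁴ molecules, 2,000-region null calibrations,
and 60-sample cohorts. These sizes put every statistic in its informative
range (e.g. the equal-base capture comparison uses a budget of ~0.35
genome-lengths, where an unfiltered library captures few islands and a
depleted one nearly all).

## Known limitations

* Idealized digestion and conversion; no partial digestion, star
  activity, or PCR duplicates.
* Pooled-count DMR testing ignores biological replication variance.
* The cohort generator plants sample-independent effects at independent
  CpGs; co-methylation structure and copy-number effects are absent.
* Synthetic genomes are compositionally two-state; real-genome site
  spacing and capture behavior are richer.
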
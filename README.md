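# rrmp — in silico reduced representative methylome profiling

Whole-genome methylation sequencing spends most of its reads on CpG-poor,
AT-rich sequence. Reduced representative methylome profiling (RRMP) avoids
that waste with a library-level trick: after enzymatic conversion of
unmethylated cytosine to thymine, the library is digested with restriction
enzymes whose recognition sites contain **only A and T** — MseI (`TTAA`)
alone ("1-cut"), or MseI + MluCI (`AATT`) + SspI (`AATATT`) + PsiI
(`TTATAA`) ("4-cut"). Conversion floods AT-rich background fragments with
new T's, so they acquire sites and are cut away, while CpG-dense fragments
(islands, promoters) survive and dominate the sequenced library. Because
digestion happens after adapter ligation, surviving molecules keep their
original ends and lengths — for plasma cfDNA, the ~170 bp nucleosomal
fragment signature stays intact.

`rrmp` models this process end to end in silico and ships the downstream
analytics used with such data. It is written for methods developers and
analysts who want to study enzyme panels, depletion behavior and the
statistics on controlled synthetic inputs, or to apply the in silico
digestion to their own converted reads.

The package provides:

* **Synthetic genomes** with CpG-island/AT-background architecture,
  island-anchored TSS and promoters (1 kb up / 500 bp down), shores and
  shelves, and ground-truth per-CpG beta values (`simulate_genome()`).
* **Library simulation**: cfDNA or sheared-gDNA fragmentation, per-molecule
  CpG methylation states drawn Bernoulli(β), strand-resolved C→T
  conversion, and the "more than 3 CHs" incomplete-conversion filter
  (`fragment_genome()`, `convert_molecules()`, `filter_non_conversion()`).
* **In silico digestion**: exact site scanning in converted sequence space,
  per-strand genome site maps, molecule-level digestion, FASTQ depletion of
  external converted reads, and coverage as a function of inter-site
  distance (`scan_sites()`, `converted_site_map()`, `digest_library()`,
  `deplete_reads_insilico()`, `intersite_coverage_profile()`).
* **Enrichment analytics**: per-CpG coverage tracks (bismark-coverage
  dialect I/O), element capture at ≥100× combined coverage, nested
  downsampling saturation curves, element read fractions, fragment-length
  statistics.
* **Methylation statistics**: 100-kb window aggregation, per-CpG
  concordance (Pearson r and the |Δβ| > 0.5 discordant fraction), a DMR
  caller (Fisher exact on pooled counts; thresholds as commonly printed:
  p < 1e-7 with Δβ > 0.5, p < 0.05 with Δβ > 0.2 or 0.33), one-vs-rest
  differential promoters with BH q values, and hypomethylation–ChIP-peak
  association tests.
* **A cfDNA cancer classifier**: cohort QC (sites >100× in >80% of
  samples; samples with >20% shallow sites excluded), TSS ± 2 kb locality
  and variance ≥ 0.009 feature filtering, leave-one-out ridge logistic
  regression with in-fold feature selection, tumor scores and ROC/AUC
  (`qc_filter()`, `feature_prefilter()`, `loo_classify()`, `roc_auc()`),
  plus a synthetic two-group cohort generator with a tumor-fraction
  mixture (`simulate_cohort()`).

## Worked example

```r
library(rrmp)

sim   <- simulate_genome(n_islands = 20, seed = 1)          # ~150 kb genome
frags <- fragment_genome(sim$genome, "cfdna", n_fragments = 8000, seed = 2)
mols  <- convert_molecules(frags, sim$genome, sim$profile,
                           conversion_params(seed = 3))
kept  <- filter_non_conversion(mols, max_ch = 3)$retained
dig   <- digest_library(kept, enzyme_panel("one_cut"))

length(dig$retained) / length(kept)
#> [1] 0.0801
ann <- list(cpg_island = sim$annotation$cpg_island)
read_fraction_by_element(kept,        ann)$fraction
#> [1] 0.1832
read_fraction_by_element(dig$retained, ann)$fraction
#> [1] 0.9891
fragment_length_stats(dig$retained)$mode
#> [1] 173
```

One-cut digestion discards ~92% of this library — almost exclusively
AT-rich background molecules — so the island read fraction jumps from 18%
to 99%, while the retained molecules keep the cfDNA ~170 bp length mode.
Capture analysis makes the economics explicit: subsampling both libraries
to the same base budget and asking which CpG islands reach ≥100× combined
(summed) CpG coverage,

```r
budget <- round(0.35 * sum(Biostrings::width(sim$genome)))
isl <- sim$annotation$cpg_island
saturation_curve(dig$retained, isl, budget, threshold = 100, seed = 4)$captured
#> [1] 20
saturation_curve(mols,         isl, budget, threshold = 100, seed = 4)$captured
#> [1] 2
```

the depleted library captures all 20 islands where the unfiltered one
captures 2. The end-to-end pipeline (`run_pipeline(rrmp_config(...))`)
composes these stages and writes a JSON summary, a bismark-style coverage
track, a BED6 site map and the saturation table; a thin command-line
wrapper is installed at `system.file("cli", "rrmp.R", package = "rrmp")`
with `digest`, `pipeline` and `classify` subcommands.

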
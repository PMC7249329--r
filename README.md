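# ladmeth

Integrative analysis of epigenetic deregulation at lamina-associated
domains (LADs) in premature-aging fibroblasts.

Progeroid fibroblasts (e.g. Hutchinson–Gilford progeria) accumulate
coordinated changes in DNA methylation, chromatin accessibility and gene
expression at genomic regions in contact with the nuclear lamina.
`ladmeth` is an R toolkit for quantifying exactly that: it tests
Infinium EPIC beta values for differential methylation, asks whether the
changes concentrate in LADs and related chromatin strata, subtypes
patients by their methylome, estimates epigenetic age in culture, and
integrates methylation with differential ATAC-seq peaks and expression
tables. It is aimed at epigenomics analysts who already have normalized
arrays and peak/expression tables and want the LAD-centric statistics in
one tested place.

## What it computes

* **Differential methylation** — per-probe two-group linear model with
  empirical-Bayes variance moderation: the moderated statistic
  `F = (Δmean)² / (s̃² (1/n₁ + 1/n₂))` with
  `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, prior `(d₀, s₀²)` estimated by method
  of moments on log variances (trigamma inversion), BH-adjusted. Probe
  filtering by detection p-value and sex-chromosome / SNP /
  cross-reactivity flags.
* **Bounded probe clustering** — greedy scan with max gap 500 bp and max
  span 1500 bp; the 5000 most variable clusters feed resampling
  **consensus clustering** (maxK 6, 1000 reps, 80% sample subsampling)
  with delta-area + PAC + separation-guarded selection of K, plus PCA.
* **Enrichment statistics** — signed observed/expected fold enrichment
  (`O/E` enriched, `−E/O` depleted) with capped-Yates chi-squared, Fisher
  exact tests, peak distributions across genes/promoters/enhancers/LADs,
  and stratified Δβ (LAD, solo-WCGW PMD/HMD, histone marks) with Welch
  tests.
* **Track signal** — poised-enhancer calling from paired H3K4me1 peaks
  (< 1500 bp apart), log2 ChIP/input enrichment over LAD vs inter-LAD
  segments with Wilcoxon rank-sum tests.
* **Epigenetic age** — linear clock with the piecewise log-linear age
  transform, and the passage factor
  `ρ = passage × 3.32 × log10(harvested/seeded)` (cumulative population
  doublings), with per-subgroup Δage medians.
* **Multi-omic integration** — feature-to-gene assignment, differential
  gene-set overlaps, distance-to-nearest-LAD tests, cross-study
  expression correlation.
* **Synthetic study generator** — a seeded simulator of the whole input
  bundle (tracks, beta/detection matrices, peaks, expression, clock) with
  recorded planted truth, so the complete pipeline runs and is testable
  with no external data.

## Worked example

Simulate a study with the default design (6 controls vs 9 cases in two
subgroups) and run the full pipeline:

```r
library(ladmeth)

dir <- tempfile()
simulate_study(dir, simulation_config(), seed = 1)
summary <- run_pipeline(pipeline_config(dir, file.path(dir, "out"),
                                        seed = 1))

summary$n_differential_probes
#> [1] 1443
summary$median_delta_beta_laminA
#> [1] 0.06751294
summary$laminA_fold_all
#> [1] 5.536652
summary$chosen_k
#> [1] 3
summary$peak_lad_fold_gained
#> [1] 2.287612
summary$median_delta_age
#> $case1      $case2      $control
#> [1] -1.707   [1] 10.25   [1] 0.563
```

Reading the numbers: 1443 of ~19,000 retained probes are differentially
methylated (q < 0.05); the lamin A LAD probe stratum gains a median
Δβ ≈ +0.07 (the planted +0.10 LAD effect diluted by the second subgroup's
global shift); differential probes are 5.5-fold enriched in lamin A LADs;
consensus clustering recovers the three planted sample groups; gained
accessibility peaks are ~2.3-fold LAD-enriched (planted 2.6, mildly
attenuated by universe contamination); and the two case subgroups show
median epigenetic age offsets of about +10 and −1.7 years (planted
+9.73 / −1.51 with 2-year jitter). Per-stage tables (differential probes,
subtypes, enrichment, age estimates, LAD distances) are written under
`out/`.

Individual stages are exported and run standalone: `filter_probes()`,
`fit_moderated_f()`, `bounded_cluster()`, `consensus_cluster()` /
`select_k()`, `fold_enrichment()`, `stratified_delta_beta()`,
`call_poised_enhancers()`, `lad_signal_enrichment()`, `apply_clock()`,
`geneset_lad_distance_test()`, and friends. The methods vignette
(`vignettes/lad-methylome-methods.Rmd`) documents the models, defaults
and design choices.

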
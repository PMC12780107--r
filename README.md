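# lowbiome

Analysis toolkit for **low-biomass tissue microbiomes** — cohorts where
tumor and adjacent-normal tissue yield only hundreds to a few thousand
bacterial reads per sample, contamination rivals the real signal, and
negative results are only meaningful next to an explicit power analysis.
It is written for microbiome statisticians and computational biologists
working from Kraken-style taxonomic read counts (tissue tumor–normal
studies across 16S, RNA-seq, and WGS platforms).

## What it implements

* **Hierarchical decontamination.** Curated-list removal of frequent
  sequencing contaminants with a rescue rule (listed genera encompassing
  ≥ 2 human-associated species are kept) and forced removals (default
  *Cutibacterium*), followed by recursive upward propagation: each node
  above genus level is rescaled by the retained fraction of its
  descendants at the next lower rank,

  `adjusted(v) = clade(v) × Σ adjusted(children rank below) / Σ original`,

  applied from family to the root.
* **Rarefaction-based diversity.** Exact hypergeometric expected richness
  `E[S] = Σ_j (1 − C(N−N_j, d)/C(N, d))`; median Shannon index over 100
  subsample draws; mean Bray–Curtis over 50 draws; marginal-term PERMANOVA
  (999 permutations) via `vegan::adonis2`.
* **Compositional differential abundance.** CLR transform
  (`ln(x+0.05) − mean ln(x+0.05)`), paired tumor–normal t-tests, BH/Holm
  adjustment, fixed-effect meta-analysis, Fisher's combined test,
  cross-platform concordance, marker-based cell-type scores.
* **Survival scans.** Ten-year overall survival, one stratified Cox model
  per taxon (strata: site, stage I vs II–IV, age ≤ 65 / > 65; adjusted for
  histology and age decade), BH-adjusted across taxa.
* **Two power frameworks.** Analytic paired-test power
  `Φ(β√n − C_α) + Φ(−β√n − C_α)` with minimum-detectable-effect solving,
  and simulation-based Cox power over a censored-ML log-normal baseline
  with Bender inverse-probability event times `T = S₀⁻¹(U^exp(−βz))`.
* **A synthetic cohort generator** with known ground truth (planted
  contaminants, CLR-scale tumor effects, per-taxon hazard ratios) so every
  stage — including the power calibration itself — is testable end to end.

## Worked example

```r
library(lowbiome)

cfg <- cohort_config(n_subjects = 60, platform = "RNA",
                     tumor_effect = c(g01 = 0.8),
                     contaminants = c("Contam_A", "Contam_B"),
                     contaminant_intensity = c(0, 0.5), seed = 4)
co <- generate_cohort(cfg)
co$table
#> count_table: 52 taxa x 120 samples at rank 'G'
#> total reads: 1630047; per-sample median: 11036.5

policy <- contaminant_policy(co$truth$contaminants, min_genus_reads = 5)
dec <- decontaminate_table(co$table, policy)
dec$removal
#> [1] "Contam_A" "Contam_B"

clr <- clr_transform(dec$table, pseudo_count = 0.05)
da <- paired_da_test(clr, data.frame(
  tumor  = co$metadata$sample_id[co$metadata$tissue == "tumor"],
  normal = co$metadata$sample_id[co$metadata$tissue == "normal"]))
head(da[order(da$p_value), c("taxon", "mean_delta", "t", "p_value", "p_adjusted")], 3)
#>    taxon mean_delta    t  p_value p_adjusted
#> 1    g01      1.128 7.36 6.57e-10   3.42e-08
#> 36   g36      0.318 2.03 4.65e-02   8.75e-01
#> 45   g45      0.364 1.86 6.77e-02   8.75e-01
```

The cohort is RNA-seq-like (median ~10⁴ bacterial reads per sample) with
two contaminant genera spiked into one processing batch and a CLR-scale
tumor effect of 0.8 planted on genus `g01`. Decontamination removes
exactly the spiked genera; the paired CLR test recovers the planted genus
as the only FDR-significant hit (realized mean CLR difference 1.13, the
planted 0.8 plus this cohort's sampling variation), while the other genera
stay at null-level p-values.

How detectable would a subtler shift be? The analytic framework answers
directly:

```r
min_detectable_effect(n = 385, alpha = 2.8e-4)   # 385 pairs, Bonferroni alpha
#> [1] 0.2280546
```

i.e. with 385 tumor–normal pairs a standardized paired CLR effect of
about 0.23 is the smallest detectable at 80% power.

A thin command-line wrapper over the same functions ships in
`inst/scripts/lowbiome.R` (subcommands: `simulate`, `decontam`,
`diversity`, `permanova`, `da`, `survival`, `power-paired`,
`power-survival`, `run`).

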
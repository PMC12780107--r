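---
title: "Analyzing low-biomass tissue microbiomes with lowbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing low-biomass tissue microbiomes with lowbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowbiome)
```

## The problem

Tumor and adjacent-normal lung tissue carry very few bacteria. After host
read removal and contaminant filtering, typical per-sample bacterial read
totals are on the order of a few hundred reads for whole-genome sequencing
(median around 344 in tumors), several hundred for 16S amplicon data
(around 730), and around 10^4 for RNA-seq (around 9080). At these depths,
reagent and handling contamination can dominate the real signal, sample
depth varies by orders of magnitude, and any negative finding is only
interpretable alongside an explicit power analysis. `lowbiome` packages
that whole workflow — decontamination, rarefaction-based diversity,
compositional differential abundance, survival scans, meta-analysis, and
two power frameworks — together with a ground-truth synthetic cohort
generator, so each stage can be validated end to end without access to any
restricted data.

## Decontamination model

Input is a Kraken-style taxonomic profile: per node, *clade* reads
(assigned to the node or any descendant) and *direct* reads (assigned to
exactly that node). Decontamination operates at the genus level:

1. Genus cells with fewer than a per-platform floor (2 reads for
   Bracken-adjusted DNA counts, 5 for RNA-seq) are zeroed — isolated one-
   and two-read genus calls at these depths are overwhelmingly
   false-positive assignments.
2. Genera on a curated list of frequent sequencing contaminants
   (Salter-style) are removed, **except** those encompassing two or more
   known human-associated species, which are rescued to avoid discarding
   plausibly real organisms. Force-removed genera (by default
   *Cutibacterium*, a ubiquitous skin commensal whose abundance pattern
   across platforms marks it as contamination in tissue data) are removed
   regardless of rescue.
3. The removal is propagated upward: for each node above genus level, the
   adjusted clade count is the original count times the retained fraction
   of its descendants at the next lower standard rank
   (`sum(adjusted) / sum(original)`), applied from family to the root so
   the fractions chain recursively. Counts become real-valued; rounding
   happens only on explicit export, because early rounding would break the
   conservation identity `clade = direct + sum(children clade)` that the
   tree validator enforces.

Two conventions were genuinely open and are package design choices, both
exposed as flags:

* **Zero denominators.** A node whose lower-rank descendants carry no
  reads has an undefined retained fraction. The default keeps the node's
  reads (fraction 1), so lineages observed only above genus level are not
  silently destroyed; the strict multiplicative alternative (fraction 0)
  is available via `zero_denominator = "drop"`.
* **Clade vs direct counts.** The rescaling operates on clade counts,
  because all downstream rank tables are clade-based; a `counts =
  "direct"` mode rescales direct counts by the node's own fraction
  instead.
* **Rank skipping.** For lineages missing an intermediate rank (a genus
  directly under an order), the nearest populated lower standard rank is
  used, so removals cannot leak upward through a skipped level;
  non-standard "no rank" nodes are transparent throughout.

## Diversity at a common depth

All diversity comparisons are made at a fixed rarefaction depth. Expected
richness uses the exact hypergeometric form
`E[S] = sum_j (1 - C(N - N_j, d) / C(N, d))`, evaluated with log-gamma so
large counts do not overflow. Shannon diversity (natural log by
convention; base-2 via a flag) is the **median** over 100 random
subsamples without replacement; Bray–Curtis dissimilarity
`sum|x - y| / sum(x + y)` is the **mean** over 50 subsampled distance
matrices. Subsampling uses multivariate hypergeometric draws with
per-sample RNG streams derived from a master seed, so results do not
depend on sample order. Association of metadata with beta diversity uses
marginal-term PERMANOVA (999 permutations by default) through
`vegan::adonis2(by = "margin")`: the marginal sum of squares of a term is
the drop in explained SS when the term is removed from the full model, and
the permutation p-value counts the observed statistic
(`p = (1 + #{F* >= F}) / (1 + n_perm)`), so p is never exactly zero.
Permutations are of raw sample identities; the model matrix stays fixed.

## Compositional analysis

Counts are compositional, so per-sample centered log-ratios are used:
`y_i = ln(x_i + c) - mean_j ln(x_j + c)` with pseudo-count `c = 0.05` on
the raw count matrix. The differential-abundance primitive is the paired
t-test on per-subject tumor-minus-normal CLR differences — deliberately
the same test whose power the analytic framework below describes, so
simulation and theory can be compared like for like. Degenerate taxa
(zero-variance differences) report p = 1 with a flag instead of being
dropped. Multiple testing uses Benjamini–Hochberg FDR by default, with
Holm available for family-wise control. Cross-platform pooling uses
inverse-variance fixed-effect meta-analysis, Fisher's combined probability
test for p-values, and arithmetic averaging of PERMANOVA R² across data
subsets. Marker-based cell-type scores are the median `log2(CPM + 1)` over
each marker set (the logCPM base affects only a monotone rescaling of
scores).

## Survival scans

Overall survival is censored at ten years; deaths after the horizon become
censored observations at the horizon. Baseline hazards are stratified by
study site, stage (I vs II–IV combined, for stable estimation with few
late-stage subjects), and age at diagnosis (≤65 vs >65), with adjustment
for histology and age in ten-year categories. One Cox model is fitted per
taxon with the taxon's CLR abundance as the covariate of interest,
Breslow tie handling by default (Efron via flag). Subjects with unknown
stage are dropped with a warning (listwise deletion); strata without
events simply contribute nothing to the partial likelihood; taxa whose
abundance is constant across analyzed subjects are reported as aliased
rather than tested. Taxa enter the scan only if they have at least 50
reads in at least 10% of samples (RNA-seq; the read cutoff is relaxed to
10 for 16S and WGS given their lower depth).

## Power frameworks

**Paired comparisons.** With standardized effect `beta = E(delta)/sigma`
and `n` pairs, the noncentrality parameter is `xi = beta*sqrt(n)` and the
two-sided level-`alpha` power is approximated by
`Phi(xi - C_alpha) + Phi(-xi - C_alpha)`, `C_alpha = qnorm(1 - alpha/2)`.
Both terms are kept, so power at `beta = 0` is exactly `alpha`.
`min_detectable_effect()` inverts the formula by bisection (tolerance
1e-6) seeded by the closed form `(z_{1-alpha/2} + z_{power})/sqrt(n)`.
For reference designs of 385 pairs at `alpha = 2.8e-4` / `0.01` and
n = 1279 at `3.9e-5` / `0.01`, the solutions are 0.228, 0.174, 0.139 and
0.0956.

**Survival.** A log-normal baseline `log T ~ N(mu, sigma^2)` is fitted to
observed follow-up by censored maximum likelihood
(`survival::survreg`; an events-only closed form is available as a
sensitivity flag). Event times under a hazard ratio are generated by
inverse-probability sampling, `T = S0^-1(U^exp(-beta z))` with
`z ~ N(0, 1)`, computed on the log scale so extreme hazards cannot
underflow the survival probability to zero. A configured fraction of
subjects is censored (uniform on `(0, T_i)` by default; administrative
censoring at the matching baseline quantile via flag), a Cox model is
fitted, and power is the fraction of 1000 replicates with Wald p below the
threshold. One numerical subtlety: the Cox fits inside the simulation
disable `survival`'s time-tie fuzzing (`timefix`), because exact simulated
times legitimately span many orders of magnitude and the default relative
tolerance would merge them into spurious ties. `min_detectable_hr()`
bisects the log hazard ratio with common random numbers across bisection
steps (making the estimated power curve monotone within a run) and returns
the verified upper bracket, whose estimated power meets the target by
construction.

## The synthetic cohort generator

The generator emulates the study design the analyses target: paired
tumor–normal subjects across platforms, with known ground truth recorded
alongside every cohort.

* **Depths** are log-normal, parameterized by the median (344 / 730 /
  9080 reads for WGS-, 16S-, RNA-like platforms, the reported tumor
  medians) with `sdlog = 0.6`, giving the order-of-magnitude spread seen
  in tissue data.
* **Compositions**: a cohort base composition from a Dirichlet with
  concentration 0.5 per genus (a few dominant genera, many rare), and
  per-subject compositions from `Dirichlet(20 * base)` — a total
  concentration of 20 produces the strong inter-subject variation and
  sparse rare genera characteristic of tissue microbiomes (CLR spreads of
  1–2+ units).
* **Tumor effects** are planted on the CLR scale: the effect vector is
  added to log-abundance and the composition renormalized, which shifts
  each genus's CLR by its effect minus the mean planted effect.
* **Contamination** is spiked per batch: Poisson reads at
  `intensity * depth`, split across contaminant genera, with some batches
  clean — the structure list-based decontamination is designed to remove.
* **Survival** reuses the inverse-probability generator with linear
  predictor `sum_k log_hr[k] * z_k`, where `z_k` is the taxon's true-CLR
  abundance standardized across subjects, so planted log hazard ratios are
  per standard deviation of the feature — the same convention as the
  power simulation's standard-normal covariate.

What the generator does **not** emulate: sequencing-read-level artifacts
(errors, adapters, chimeras), taxonomic misassignment, platform-specific
amplification bias, or correlated contaminant communities. Passing
recovery tests therefore demonstrates that the statistical machinery is
correct under its own assumptions at realistic depths and effect sizes —
not that any particular real dataset satisfies those assumptions.

## Validation strategy and problem sizes

The test suite checks each component against an independent oracle:
propagation against a recursive brute-force re-computation on random small
trees; expected richness against exhaustive enumeration and Monte-Carlo
subsampling; PERMANOVA against hand-worked Gower-centering arithmetic and
an explicit projection oracle, with null p-values checked for uniformity;
Cox fits against a grid-search maximizer of the Breslow partial
likelihood; the survival power simulation against the Schoenfeld
closed-form approximation in uncensored designs and against the nominal
level at zero effect. Calibration runs use desk-scale sizes chosen to keep
the whole suite fast while leaving Monte-Carlo error well inside the
asserted bands: 2000 taxon-level null tests for type-I error at
`alpha = 0.01`, 1000 replicates for survival power, 40 cohorts of 400
pairs for the power-vs-simulation comparison, and 20 runs of 600 subjects
for hazard-effect recovery. Because realized standardized effects vary
across synthetic cohorts (rare genera attenuate), the analytic comparison
averages per-case predicted power rather than evaluating power at the mean
effect.

## Known limitations

* The paired CLR t-test is the package's differential-abundance
  primitive; bias-corrected compositional methods (ANCOM-BC, ALDEx2) are
  out of scope and results for strongly compositional effects will differ.
* Statistical decontamination from negative controls (SCRuB-style) and
  batch correction (ComBat-Seq) are external steps; this package consumes
  their outputs.
* The log-normal censored ML assumes non-informative censoring; censoring
  mechanisms that depend on the event time bias the fit and no flag can
  undo that.
* UniFrac and other phylogeny-aware metrics are not provided.

## A minimal session

```{r, eval = FALSE}
cfg <- cohort_config(n_subjects = 60, platform = "RNA",
                     tumor_effect = c(g01 = 0.8),
                     contaminants = c("Contam_A", "Contam_B"),
                     contaminant_intensity = c(0, 0.5),
                     survival = list(mu = 1, sigma = 1.1,
                                     censor_fraction = 0.4,
                                     log_hr = c(g02 = 0.4)),
                     seed = 1)
run_pipeline(default_run_config("RNA", seed = 1), "run1",
             cohort = generate_cohort(cfg))
```

Every run directory is immutable and carries a manifest (configuration,
seed, MD5 of every output), so a rerun with the same configuration is
byte-identical.
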
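---
title: "Methods: multi-cohort meta-analysis of the aging gut microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort meta-analysis of the aging gut microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemicro)
```

`agemicro` integrates species-level stool metagenome count tables from
several independent cohorts spanning young, elderly and long-lived
adults, and carries them through batch correction, diversity analysis,
differential abundance, co-occurrence networks, cluster enrichment,
age-stage signature calling and interaction-shift analysis. This
vignette documents the models, the parameters that matter, the design
choices made where the method was genuinely open, and what the
simulation-based tests do and do not establish about real data.

## Data model

The substrate is a `taxa_table`: a samples × taxa matrix of
non-negative counts (or abundances), a kingdom annotation per taxon
(bacteria, fungi, archaea, viruses), and a scale tag
(`counts`, `rpm`, `relative`, `clr`). Sample metadata carry age,
gender, cohort/batch identity and read counts. Age groups are assigned
by explicit half-open interval schemes; two are bundled:
`scheme_wrc()` — W (< 62), R (62–88), C (≥ 89) — suited to the full
pooled cohort, and `scheme_yec()` — Y (< 55), E (67–89), C (≥ 96) —
the stricter post-filtering strata. The two schemes are not
interchangeable and the pipeline never picks one silently; analyses on
integer ages treat the open bounds "66 < age < 90" and "age > 95" as
67–89 and ≥ 96.

## Batch correction

Cross-cohort technical variation is aligned by a two-part conditional
quantile correction, stratified by covariates so biological signal is
not erased. Within each stratum (by default age group × gender ×
read-depth tertile) and for each taxon:

* **zero part** — each non-reference batch's zero fraction is moved
  toward the reference batch's: excess zeros are re-seeded with random
  reference quantiles, excess nonzeros are zeroed starting from the
  smallest values; which cells toggle is decided by a seeded draw;
* **nonzero part** — remaining nonzero values are mapped through their
  batch's empirical CDF onto the reference batch's empirical quantile
  function.

The reference batch is returned bit-identical, counts are rounded to
non-negative integers, and (stratum, batch) cells with fewer than
`min_stratum` samples (default 2) are left uncorrected and logged.
Depth tertiles are computed *within* batch: sequencing depth differs
systematically between cohorts, so an absolute cut would make the
stratum a proxy for the very batch label being corrected. Note that
when batch library sizes differ, aligning count distributions onto the
reference necessarily rescales per-sample read mass — that is the
point of the correction, and downstream analyses use relative
abundances of the corrected counts.

This correction is deliberately simpler than full two-part
quantile-regression approaches: the distributional alignment is
empirical rather than model-based, which makes it fully specified,
fast, and easy to reason about. The evaluation grid accepts any
externally corrected table, so a different correction can be plugged
in without touching the rest of the pipeline.

Success is quantified by `evaluate_batch_grid()`: PERMANOVA R² for
batch and for age group, under Bray–Curtis and Aitchison distances,
across five representations (raw counts, corrected counts, RPM,
corrected RPM, RPM of corrected counts). A useful correction drives
the batch R² down by an order of magnitude while the age-group R² is
retained; the package's acceptance checks require the drop in ≥ 9/10
simulated cohorts and retention of at least half the age-group R².

## Diversity

Alpha diversity is Shannon entropy (nats) and bias-corrected Chao1
(`S_obs + F1(F1−1)/(2(F2+1))`), the latter defined only on integer
counts since singleton counts are meaningless after normalization.
Before pooling, studies are filtered for alpha-diversity homogeneity:
while the Kruskal–Wallis test across studies is significant (default
level 0.05) and fewer than `max_removed_fraction` (default 30%) of
samples have been removed, the single sample whose removal maximizes
the KW p is removed. This greedy rule is deterministic and fully
logged; it is one admissible reading of a filter described only by its
test. Per-sample removal (not whole-study trimming) is the only mode
implemented. Because the KW statistic is rank-based, a lone outlier
rarely drives significance by itself; the filter earns its keep when a
study subset is systematically shifted.

Beta diversity uses Bray–Curtis on relative abundances and the
Aitchison distance (Euclidean on CLR). The CLR pseudocount is half the
smallest nonzero relative abundance in the table — table-wide, so the
transform is deterministic and rows with zeros remain comparable.
PCoA is classical scaling of the Gower-centered −D²/2 matrix; negative
eigenvalues are reported and their axes dropped. One-way PERMANOVA is
implemented from its sum-of-squared-distance definition with seeded
label permutations and the (1 + more-extreme)/(1 + n_perm) convention,
so p is never 0; the R² needs no permutations and `n_perm = 0` skips
the test. Dispersion homogeneity uses distance-to-centroid in
principal-coordinate space (via `vegan::betadisper`), seeded.

## Differential abundance

Each taxon is fit by OLS on total-sum-scaled, log2-transformed
abundance with a per-feature pseudocount of half its minimum nonzero
relative abundance, against a group indicator (plus optional
covariates; the default is none, and this choice is recorded in every
output header). A two-sided t-test on the group coefficient gives p,
BH-FDR across taxa gives q, and DAMs are called at `q < 0.25`
(strict). Prevalence below 10% excludes a taxon before testing;
zero-variance features are excluded and logged. The three pairwise
comparisons (Y vs E, Y vs C, E vs C) are fit separately rather than as
one three-level model, matching how the per-comparison DAM sets and
their Venn overlap are defined. Fold-change tables use pseudocount 1
on the count scale (`log2((mean+1)/(mean+1))`) and per-sample heatmap
values `log2(count + 1)`.

## Networks, enrichment, signatures, shifts

Per age group, Pearson correlations over that group's samples define a
graph whose edges must satisfy `p < 0.05` and `|r| > 0.3`, both
strict, with p from the t transform `t = r√((n−2)/(1−r²))`.
Zero-variance taxa are dropped per group. Communities come from
Pons–Latapy walktrap (steps = 4, the reference implementation's
default) on the unweighted thresholded graph, cut at maximum
modularity; isolated nodes are singletons; "large" clusters have
membership strictly greater than 10. The abundance scale is
configurable; relative abundance is the pipeline default, while the
planted-rewiring benchmark below uses CLR (see *Numerical behavior*).

DAM sets are tested for over-representation in each large cluster with
the upper-tail hypergeometric p, `P[X ≥ k]`,
`X ~ Hypergeom(N, K, n)`; the default background N is the union of all
large-cluster nodes with the DAM set — the most literal reading of
"cluster nodes combined with the DAMs" — with all-network-nodes and
per-cluster backgrounds selectable. BH is applied across clusters
within one (network, DAM set) pair; the multiplicity convention is a
package choice, recorded here because the method description leaves it
open.

A taxon is an age-stage signature of group G when it is a DAM in at
least one pairwise comparison involving G and its mean corrected
relative abundance in G strictly exceeds both other group means. The
"at least one" reading is deliberate: requiring both comparisons would
cap each group's signatures at the three-way-common DAM count, which
is inconsistent with one group's signatures outnumbering the common
set by an order of magnitude in practice. Signature sets are disjoint
by construction (only one group can be the strict maximum).
Interaction shifts compare a focal taxon's within-cluster neighbor
sets across the group networks: presence, in-cluster degree, kingdom
breakdown and pairwise Jaccard; a taxon absent from a network is a
reported outcome, not an error, and a focal taxon in a small
(≤ 10-member) cluster uses that cluster with a flag.

## The simulator and what the tests show

`generate_cohort()` draws, for sample *i* and taxon *j*,

log λ_ij = base_j + Σ group effects + batch shift_{b(i),j} +
Σ_k loading_jk · z_ik + ε_ij,

with z_ik a standard-normal latent factor per active correlation block
and ε ~ N(0, σ_noise); counts are multinomial draws of the sample's
log-normal library size from softmax(log λ); per-batch excess
zero-inflation is applied afterwards. The logistic-normal multinomial
construction was chosen over independent negative binomials because
planted correlation blocks must survive compositional closure for the
network stage to have anything to find. Zero-inflation is applied per
batch, not per group, so removing it is the batch correction's job,
not the differential-abundance stage's.

Defaults, chosen once as the package's study conditions: 3 batches × 3
age groups × 20 samples per cell; 300 taxa split 220 bacteria / 40
viruses / 25 fungi / 15 archaea (roughly the multi-kingdom balance of
species-level gut profiles); per-taxon baseline spread `base_sdlog`
1.0 with kingdom offsets (bacteria + 2, viruses + 0.5, fungi 0,
archaea − 0.5), spanning about four orders of magnitude in relative
abundance; library-size medians 1.2e5 / 2e5 / 5e4 reads with sdlog
0.35 — scaled-down stand-ins that keep the cohorts' relative depth
spread rather than their absolute terabyte scale; batch shift
σ = 1.0 per (batch, taxon) with batch 1 the undistorted reference;
σ_noise = 0.5; zero-inflation 0 / 0.05 / 0.10 across batches. Planted
effects are placed on taxa whose baseline is shifted down (the
`base_shift` argument): a fold change planted on an abundant taxon
drags every other relative abundance with it through closure, so
without this the "null" taxa would not be null under total-sum
scaling — an artifact of benchmark construction, not a property of the
method under test.

Benchmark problem sizes are likewise package choices: differential
abundance uses n = 40/group with 30 planted effects (log2FC ± 3) among
300 taxa; the rewiring benchmark uses n = 200/group with ~380 taxa,
8-member blocks at loading 2, and CLR-scale correlations. Two effects
motivated the latter: at small n the `p < 0.05` edge rule alone admits
a few percent of all null pairs, and on relative abundances the shared
denominator induces correlations up to the 0.3 threshold between
abundant taxa (and a CLR mean-leakage analogue appears if blocks are
large relative to the taxon pool). n = 200 puts the null correlation
tail (≈ 2.6e−5 past |r| = 0.3) below one spurious edge per network, so
the benchmark isolates rewiring recovery from sampling noise.

What passing these tests shows: the machinery recovers planted batch
distortion, fold changes, blocks, signatures and rewiring under a
compositional count model with realistic depth and kingdom structure.
What it does not show: robustness to phylogenetically structured
effects, longitudinal sampling, read-level artifacts (the pipeline
starts from count tables), or the far heavier tails and zero patterns
of real gut metagenomes.

## Numerical behavior and known limitations

* **Determinism.** Every stochastic step takes a seed;
  `run_pipeline()` derives per-stage seeds from one global seed by a
  fixed stage-name hash, and identical configs reproduce
  byte-identical outputs.
* **Degenerate inputs.** All-zero samples stay zero under TSS/RPM
  (with a warning) and are an error under CLR; an all-identical
  distance matrix is an error for PERMANOVA (SS_total = 0) and returns
  zero dispersions for the dispersion test; edgeless networks become
  all-singleton partitions; ties in the rank tests use the standard
  corrections, and an all-tied Kruskal–Wallis input returns H = 0,
  p = 1 by convention.
* **Strictness.** Every published threshold is strict: `q < 0.25`,
  `p < 0.05`, `|r| > 0.3`, membership > 10. Boundary values do not
  qualify.
* **False signatures are expected at q < 0.25.** With a calibrated
  per-feature test, BH at level 0.25 over ~300 features in the
  presence of a few strong signals admits nulls with p below roughly
  `(#signals × 0.25)/m`; in the planted-signature benchmark this means
  a handful of false signatures per cohort (and, under a global null,
  at least one spurious DAM in roughly a quarter of comparisons). This
  is a property of the published DAM rule itself, not of the
  implementation; the signature stage therefore reports evidence per
  taxon so downstream users can apply stricter thresholds.
* **The hybrid "Bray–Curtis on CLR" reading.** One figure caption in
  the motivating analysis combines Bray–Curtis with CLR-transformed
  profiles; Bray–Curtis on signed values is ill-defined, so the
  package implements the two metrics separately (BC on relative
  abundance, Euclidean on CLR) and does not reproduce the hybrid.
* **Correction limits.** Quantile alignment cannot distinguish batch
  from biology inside a stratum; covariates must carry the biology.
  Cells below `min_stratum` stay uncorrected, so heavily unbalanced
  designs degrade toward no-op rather than overcorrection.
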
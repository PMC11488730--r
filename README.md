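# agemicro

Multi-cohort, multi-kingdom meta-analysis of the aging gut microbiome,
as a tidyverse-native R pipeline. Public metagenomic cohorts of young,
elderly and long-lived adults differ wildly in sequencing depth, library
prep and processing; pooling them naively makes cohort identity — not
age — the dominant axis of community variation. `agemicro` provides the
full analysis chain that turns per-sample species count tables from
several such cohorts into age-stage microbial signatures and
interaction-shift calls, with every stochastic step seeded and every
stage testable against planted ground truth.

The pipeline stages, each usable on its own:

1. **Batch correction** — a two-part stratified quantile correction:
   within covariate strata (age group × gender × within-batch read-depth
   tertile), each non-reference batch's per-taxon zero fraction is moved
   toward the reference batch's, and the nonzero values are mapped
   through their empirical CDF onto the reference quantile function.
   An evaluation grid quantifies success as PERMANOVA R² for batch and
   for age group, over five data representations (raw counts, corrected
   counts, RPM, corrected RPM, RPM of corrected counts) × two community
   distances (Bray–Curtis, Aitchison).
2. **Diversity** — Shannon and bias-corrected Chao1 alpha diversity, an
   inter-study homogeneity filter (greedy per-sample removal maximizing
   the Kruskal–Wallis p across studies), Bray–Curtis and Aitchison
   (Euclidean-on-CLR) distances, principal-coordinate analysis, one-way
   PERMANOVA with seeded permutations, and multivariate dispersion
   tests.
3. **Differential abundance** — per-taxon linear models on total-sum
   scaled, log2-transformed abundances (half-minimum-nonzero
   pseudocount per feature), pairwise between age groups, BH-FDR, and a
   strict `q < 0.25` DAM (differentially abundant microbe) call, with
   Venn overlaps and `log2(reads+1)` fold-change tables.
4. **Co-occurrence networks** — per-age-group Pearson correlation
   graphs keeping only edges with `p < 0.05` **and** `|r| > 0.3`
   (both strict), walktrap community detection, and cluster summaries
   (large cluster = membership > 10).
5. **Enrichment, signatures, interaction shifts** — hypergeometric
   over-representation of DAM sets in network clusters (background =
   union of large-cluster nodes and the DAM set), the age-stage
   signature rule (DAM in ≥ 1 comparison involving group G **and**
   strictly highest mean abundance in G), and cross-network comparison
   of a focal taxon's within-cluster neighborhood (degree, kingdom
   breakdown, Jaccard overlap).

A seeded logistic-normal multinomial simulator (`synthetic_config()` /
`generate_cohort()`) generates multi-batch, multi-kingdom cohorts with
planted batch shifts, group effects, correlated taxon blocks, age-stage
signatures and network rewiring, and emits the ground truth needed to
test every stage.

## The statistics, briefly

For sample *i* and taxon *j* the simulator draws counts
multinomially from a softmax composition over
log λ\_ij = base\_j + group effect + batch shift\_{b(i),j} +
Σ\_k loading\_jk z\_ik + ε\_ij, so planted correlation blocks survive
compositional closure. PERMANOVA uses SS\_total = Σ\_{i<j} d²\_ij / N,
SS\_within = Σ\_g Σ\_{i<j∈g} d²\_ij / n\_g,
F = (SS\_B/(a−1))/(SS\_W/(N−a)), R² = SS\_B/SS\_total, and
p = (1 + #{F\_perm ≥ F\_obs})/(1 + n\_perm). Cluster enrichment is
P[X ≥ k] with X ~ Hypergeometric(N, K, n), BH-adjusted across clusters.

## Worked example

```r
library(agemicro)

cfg <- pipeline_config(
  seed = 42, out_dir = "demo_run",
  simulation = demo_config(seed = 1, samples_per_cell = 20),
  focal_taxa = "archaea_sp_010"  # the demo's planted rewired taxon
)
man <- run_pipeline(cfg)

man$results$eval_grid |>
  dplyr::filter(metric == "bray_curtis", factor == "batch")
#> # A tibble: 5 x 6
#>   representation       metric      factor      R2 pseudo_F p_value
#>   <fct>                <chr>       <chr>    <dbl>    <dbl>   <dbl>
#> 1 taxa_reads           bray_curtis batch  0.414     62.5     0.005
#> 2 corrected_taxa_reads bray_curtis batch  0.00918    0.820   0.665
#> 3 rpm                  bray_curtis batch  0.318     41.3     0.005
#> 4 corrected_rpm        bray_curtis batch  0.00908    0.811   0.77
#> 5 rpm_after_correction bray_curtis batch  0.00952    0.851   0.69

man$results$shifts[["archaea_sp_010"]]$jaccard
#> # A tibble: 3 x 3
#>   group_a group_b jaccard
#>   <chr>   <chr>     <dbl>
#> 1 Y       E         0.172
#> 2 Y       C         0
#> 3 E       C         0
```

Before correction, batch identity explains ~41% of Bray–Curtis
community variation in this simulated three-cohort design; after the
quantile correction it explains under 1% (and is no longer
significant), while the age-group R² (not shown) is retained.
Downstream, `man$results$signatures` lists the recovered age-stage
signatures with their evidence, and the interaction-shift table shows
the planted rewired taxon's young-group and centenarian-group
neighborhoods sharing no members. Every output is also written
under `demo_run/` as TSV/JSON with a parameter header line, plus a
manifest with checksums; re-running the same config reproduces the
files byte-for-byte.

`autoplot()` works on the main results (`eval_grid`, `pcoa_result`,
`da_result`, `interaction_shift`), and `tidy()`/`glance()` on the
fitted objects.

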
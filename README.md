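# senescape

Quantifying cellular senescence burden in brain tissue from single-nucleus
RNA-seq and imaging mass cytometry (IMC).

## The problem

Senescent cells accumulate in the ageing brain and are implicated in
Alzheimer's disease (AD), particularly in microglia near β-amyloid plaques.
Measuring that burden from data requires a chain of small, well-defined
statistical steps that are usually scattered across ad-hoc scripts:

1. **Per-nucleus gene-set scoring.** For a senescence gene set *S* and a
   per-cell ranking of genes by expression, the rank-based AUC score is the
   area under the recovery curve *y(i) = #{g ∈ S : rank(g) ≤ i}* accumulated
   over the top *maxRank = ⌈0.05 · n_genes⌉* ranks, normalised by the
   top-packed maximum *Σᵢ min(i, |S|)* so that scores lie in [0, 1]. A
   bin-matched control "module score" (mean expression over *S* minus the
   mean over expression-matched control genes) is provided as a second
   method.
2. **Senescent-nucleus calling.** Within a stratum (cell type, by default),
   a nucleus is senescent when its score exceeds
   `median + 3 × MAD` (MAD normal-consistent, 1.4826 scaling).
3. **Group contrasts.** Per-sample senescent proportions (samples with < 3
   cells per stratum excluded) compared between AD and non-diseased control
   (NDC) donors with Wilcoxon rank-sum tests, rank-biserial effect sizes
   r = 2·U₁/(n₁n₂) − 1 with bootstrap CIs, and BH-adjusted p-values;
   Pearson regression of per-sample quantities against β-amyloid (4G8⁺)
   load.
4. **Age model.** A continuous linear-plateau fit
   *y = a + b·min(x, c)* of mean senescence score against donor age, with a
   profiled breakpoint *c* and an F-test against the flat (intercept-only)
   null.
5. **Meta-analysis.** Per-sample mean scores reduced to Hedges' *g* per
   dataset and pooled with a DerSimonian–Laird random-effects model
   (τ², I², z, direction counts).
6. **IMC spatial analysis.** QC trimming (lowest-1% ROIs, then lowest-1%
   cells per ROI), marker positivity calling (fixed / quantile / Otsu
   thresholds), senescent proportions per cluster, and peri-plaque
   classification of microglia within 10 µm of a plaque object (centroid
   distance, or label-mask dilation).

Every stage is validated against seeded synthetic generators with known
ground truth (planted senescent fractions, plaque geometry, positivity
boosts), which double as a test bed for the whole pipeline.

## Worked example

```r
library(senescape)

sim    <- simulate_expression(expression_sim_config(seed = 42))
ds     <- normalise_expression(sim$dataset)
scores <- score_cells(ds, list(CSP = sim$gene_set), method = "auc", seed = 42)
calls  <- call_senescent(scores, ds$cell_meta)        # median + 3 MAD per cell type
props  <- sample_proportions(calls, ds$cell_meta)     # per-sample proportions
contrast_proportions(props, stratify_by = "cell_type", seed = 42)
#> # A tibble: 3 × 8
#>   cell_type    n1    n2     U  p_value rank_biserial  ci_low ci_high
#>   <chr>     <int> <int> <dbl>    <dbl>         <dbl>   <dbl>   <dbl>
#> 1 Astro         8     8  33.5 0.914           0.0469 -0.516    0.594
#> 2 ExN           8     8  49   0.0562          0.531   0.0625   1
#> 3 Micro         8     8  64   0.000155        1       1        1
```

The generator plants a senescent microglial fraction of 0.25 in AD versus
0.05 in NDC donors (0.02 background elsewhere); only the microglial
contrast is significant (exact Wilcoxon p = 1.6e-4, rank-biserial 1: every
AD sample exceeds every NDC sample), and the recovered per-arm mean
proportions are close to the planted fractions:

```r
dplyr::filter(props, cell_type == "Micro", !excluded) |>
  dplyr::group_by(diagnosis) |> dplyr::summarise(mean_prop = mean(proportion))
#>   diagnosis mean_prop
#> 1 AD           0.254
#> 2 NDC          0.0673
```

Gene sets are read from GMT (`read_gmt()`, sets under 10 genes dropped), a
bundled example lives at
`system.file("extdata/senescence_sets.gmt", package = "senescape")`, and
expression data round-trip through MatrixMarket + sidecars
(`read_expression()` / `write_expression()`). The imaging side is exercised
the same way: `simulate_imaging()` → `call_markers()` → `qc_trim()` →
`classify_peri_plaque()` → `peri_vs_nonplaque_contrast()`. `run_pipeline()`
chains every stage from one (YAML-able) config into a directory of stage
CSVs plus a provenance manifest. Each fitted object (`lp_fit`,
`meta_result`) supports `tidy()` / `glance()`, and `autoplot()` /
`plot_*()` functions draw score distributions, proportion boxplots, forest
plots and ROI maps.

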
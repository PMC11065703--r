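---
title: "Methods: quantifying senescence burden with senescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying senescence burden with senescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescape)
library(dplyr)
```

senescape turns post-QC single-nucleus expression matrices and segmented
IMC cell tables into per-cell senescence scores, senescent-cell calls,
group-level contrasts, an age model and a cross-dataset meta-analysis. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where the procedure was genuinely open.

## Rank-based AUC scoring

For each cell, genes are ranked by descending expression
(`rank_genes_per_cell()`). Single-nucleus matrices are zero-inflated, so
most genes tie at zero and the tie policy is material: the default breaks
ties by a seeded uniform shuffle within each tie group, so an undetected
gene's rank is a draw from its tie block rather than an artefact of row
order. The deterministic alternative (`ties = "average"`, midranks) is
exposed because it makes scores reproducible without a seed; with midranks,
a gene counts toward the recovery curve only from the first integer rank it
reaches (the `ceiling` in the area formula).

`auc_score()` accumulates the recovery curve
$y(i) = \#\{g \in S: \mathrm{rank}(g) \le i\}$ over
$i = 1 \dots \mathrm{maxRank}$, with
$\mathrm{maxRank} = \lceil f \cdot n_\mathrm{genes} \rceil$ and $f = 0.05$
by default — the usual convention of capping the AUC at the top 5% of the
ranking. The raw area $\sum_i y(i)$ is normalised by the top-packed maximum
$\sum_i \min(i, |S_\mathrm{matched}|)$, so scores live in $[0, 1]$, 1 means
"every matched set gene packed at the top", and thresholds transfer across
gene sets of different sizes. `ceiling` guarantees $\mathrm{maxRank} \ge 1$
for any $f \in (0, 1]$. A set with no matched gene scores 0 with a warning
rather than erroring: curated senescence sets routinely contain symbols
absent from a given matrix, and unmatched symbols are counted, not fatal.
Gene symbols are matched case-sensitively after whitespace trimming.

Because ranks are invariant to any per-cell monotone transform, AUC scores
are identical on raw counts and on library-size log-normalisation
(`normalise_expression()`, `log1p` of counts scaled to 10,000). The scoring
default is the log-normalised form, which is what "normalised data" means
everywhere in the package; the dataset carries a flag recording which form
it holds, and the module score below genuinely requires the log scale.

## Bin-matched module scores

`module_score()` implements the aggregate-expression alternative: genes are
split into `n_bins = 24` bins of dataset-wide mean expression, each set
gene draws `n_ctrl = 100` seeded control genes from its bin, and a cell's
score is its mean log-expression over the set minus the mean over the
pooled controls. Two deliberate details:

* controls are drawn from the bin **excluding the set genes themselves**.
  This makes the score exactly shift-equivariant (adding a constant to the
  set genes raises every score by that constant) and keeps the control pool
  a true background; including signal genes among controls would shrink
  planted effects.
* when a bin holds fewer than `n_ctrl` candidates the draw is with
  replacement, so small matrices never fail.

The score is unbounded and centred near zero under the null; it is used for
visualisation-style aggregation, while calling and contrasts default to the
AUC score.

## Calling senescent nuclei

`call_senescent()` thresholds scores at
$\mathrm{median} + k \cdot \mathrm{MAD}$ within a stratum, $k = 3$, with
the normal-consistent MAD (constant 1.4826) so that on Gaussian scores the
rule calls approximately the $1 - \Phi(3) \approx 0.00135$ upper tail. The
raw-MAD convention is available via `mad_scale = 1`. Calls are strictly
greater-than: when the MAD degenerates to zero (mostly tied scores) the
threshold collapses to the median and only strict exceedances are called,
so an all-tied stratum produces no calls rather than half the stratum.

The threshold stratum defaults to cell type **pooled across diagnosis and
samples**. Cross-group comparisons of senescent proportions only make sense
against a common yardstick; stratifying by diagnosis would re-centre each
arm and absorb exactly the effect being measured. Per-region or per-sample
stratification is available through `group_by` for sensitivity analyses.
Strata with fewer than two cells cannot support a spread estimate and are
assigned all-`FALSE` calls with a warning.

One calibration property is worth stating precisely, because it bounds what
the rule can do: on a contaminated score distribution
$(1-\pi)\,N(0,1) + \pi\,N(8,1)$ the contamination inflates the mixture MAD,
so the large-sample expected call rate sits slightly below $\pi$ — the
effect is negligible at $\pi \le 0.1$ but reaches about $-0.008$ at
$\pi = 0.3$ (the threshold solves to ≈ 6.1 rather than ≈ 3.1). The test
suite therefore checks the implementation against the analytic mixture
expectation, not against $\pi$ itself at high contamination.

`sample_proportions()` aggregates calls to per-(sample, stratum) counts and
exact ratios. Strata observed in fewer than `min_cells = 3` cells are
flagged excluded rather than dropped silently — the same under-3-cells rule
the IMC side uses — and excluded rows keep their reason so contrasts can
report what was skipped.

## Contrasts and regression

`wilcoxon_rank_biserial()` reports the Mann–Whitney U with midrank tie
handling, a p-value that is exact when both arms have ≤ 10 observations and
no ties (full enumeration is cheap there) and otherwise the normal
approximation with continuity and tie correction, and the rank-biserial
correlation $r = 2U_1/(n_1 n_2) - 1 = P(x>y) - P(x<y)$. Confidence
intervals default to a seeded 2,000-resample percentile bootstrap
(each arm resampled independently); a normal approximation on the
$\operatorname{atanh}$ scale is available for speed. A completely tied
pooled sample has zero rank variance and carries no evidence, so its
p-value is reported as 1. Tests default to two-sided.
`contrast_proportions()` maps this over (cell type, region) strata, AD arm
first, skips strata with fewer than two usable samples per arm, and
appends BH-adjusted p-values (`bh_fdr()`, standard step-up).
`pearson_regression()` is the plain Pearson/OLS pairing used for
fraction-versus-amyloid-load panels, with a t-distributed p on $n-2$
degrees of freedom and explicit zero-variance errors.

## The linear-plateau age model

`fit_linear_plateau()` fits $y = a + b \cdot \min(x, c)$ — senescence score
rising linearly with age to a breakpoint $c$, flat beyond it, continuous at
$c$. For fixed $c$ the model is linear, so $c$ is profiled over a dense
grid (200 points spanning the observed ages, plus the observed ages
themselves) with closed-form OLS at each candidate; the minimum-RSS fit is
kept, smallest $c$ on ties. The objective is piecewise-quadratic in $c$
with kinks at data points, which is why grid profiling was chosen over
derivative-based optimisation: it is exact to grid resolution, robust and
reproducible. The p-value compares the 3-parameter fit to the
intercept-only model with an F statistic on $(2, n-3)$ degrees of freedom —
i.e. it tests for *any* age trend, which matches how the model is used:
asking whether the age association present in controls disappears in
disease. (Testing against the simple linear model instead would ask a
different question — whether the plateau improves on a straight line.) At
least 5 distinct ages are required; identical scores return slope 0 and
p = 1. The fit is affine-equivariant: rescaling scores rescales $a, b$ and
leaves $c$ and the p-value unchanged.

## Random-effects meta-analysis

The unit of analysis is the donor, not the nucleus: per-nucleus scores are
averaged per sample (`mean_score_per_group()`), each dataset is reduced to
Hedges' $g$ (Cohen's $d$ with the small-sample factor
$J = 1 - 3/(4(n_1+n_2)-9)$ and the standard large-sample variance), and
`pool_random_effects()` pools with the closed-form DerSimonian–Laird
estimator: $\tau^2 = \max(0, (Q - (k-1))/C)$, inverse-variance weights
$1/(se_i^2+\tau^2)$, a normal z test, $I^2$, and the count of datasets with
$g > 0$. DL was chosen over likelihood-based estimators because it is the
standard closed-form baseline, exactly testable against hand evaluation,
and adequate for the package's purpose of direction-and-magnitude
consistency across cohorts; with $k = 1$ the pooled effect degenerates to
that dataset's $g$ with $\tau^2 = 0$.

## IMC quantification and plaque geometry

Coordinates are micrometres with the origin at the ROI top-left and y
increasing downward, matching label-mask rasters; a mask pixel $(i, j)$ has
its centre at $((j-\tfrac12)s, (i-\tfrac12)s)$ for scale $s$ µm/px.

`qc_trim()` applies the two-stage 1% trim: ROIs in the lowest 1% of mean
senescence-marker expression (computed across **all** ROIs — the
alternative of trimming within sample is configurable upstream of this
function by splitting the table), then, per remaining ROI, cells in the
lowest 1% of their defining cell-type-marker intensity (the maximum over
the cell-type channels). Quantiles use the type-1 (order-statistic)
definition and removal is inclusive at the cutoff, so ties at the cutoff
are all removed — a determinism choice; re-applying the first pass's
cutoffs (`cutoffs` argument) removes nothing new.

`call_markers()` replaces pixel-classifier positivity with three explicit
threshold rules (fixed intensity, global or per-ROI quantile, Otsu on log
intensity), with the realised thresholds recorded on the result: trained
pixel classifiers are not reproducible from a description, thresholds are.
Positivity is strict (`intensity > threshold`).
`senescent_proportion_per_cluster()` forms, per (sample, cluster), the
ratio of cells co-expressing the cluster's cell-type marker and ≥ 1
senescence marker to all cells positive for the cell-type marker, summing
ROI counts to sample level before the ratio and excluding clusters under 3
cells.

`classify_peri_plaque()` labels a cell peri-plaque when it lies within
`radius_um = 10` µm of a plaque, inclusive at exactly 10.0 (an explicit
edge rule; the emulated procedure dilates plaque objects by 10 µm and keeps
overlaps, and dilation includes its boundary). Centroid mode measures
continuous distance to the nearest disk boundary (0 inside). Mask mode
reproduces the raster procedure: a cell is peri-plaque iff its centroid
pixel falls inside the plaque labels dilated by a disc of
`radius_um / scale` pixels, computed as the nearest-plaque-pixel distance,
which is mathematically the same dilation without a discrete brush's
rounding ambiguity. The two modes agree on disk plaques to within one pixel
at 1 µm/px. ROIs without plaques yield `distance_um = Inf` and no
peri-plaque calls. `peri_vs_nonplaque_contrast()` compares per-sample
marker-positivity proportions between compartments among microglia with a
paired Wilcoxon signed-rank test.

## What the synthetic generators emulate — and what they do not

`simulate_expression()` draws negative-binomial counts (gene-level
log-normal baseline means, dispersion `size = 2`, mild log-normal cell-type
signatures) for two arms of 8 donors × 150 nuclei over a
Micro/Astro/ExN mixture (0.4/0.3/0.3), with a planted senescent
sub-fraction per (arm, cell type) whose 80 senescence-set genes are
amplified `fold_change = 4`-fold; per-sample amyloid load is linear in the
realised microglial senescent fraction plus Gaussian noise, and donor ages
are uniform (controls 50–100 y). Defaults are fixed once as the package's
study conditions: the planted fractions (AD microglia 0.25, NDC 0.05,
background 0.02) mirror the case/control structure the methods target, and
the panel size (2,000 genes, 80-gene set) is in the realistic range for a
post-QC matrix and a curated senescence pathway — materially smaller panels
make the null AUC distribution coarse and skewed, which is a property of
tiny toy panels rather than of the data the package is meant for.
`simulate_imaging()` lays out 4 ROIs of 500 × 500 µm per donor (the
standard acquisition layout), ~250 uniformly placed cells per ROI,
non-overlapping disk plaques (log-normal radii, median 12 µm), log-normal
channel intensities around separated positive/negative modes, and boosts
GLB1/p16 positivity from 3% baseline to 30%/15% within 10 µm of a plaque.

The generators deliberately omit ambient RNA, doublets, batch effects,
spatial intensity gradients, cell-shape/segmentation error and spillover —
upstream QC is assumed done. Passing tests therefore demonstrate that the
statistics recover planted truth under a clean generative model, not that
they are robust to artefacts the pipeline never claims to handle.

Problem sizes used by the test-suite simulations (100 + 100 pipeline
replicates at the default config; 10⁵-score calibration draws; 200 plateau
replicates of 40 donors; 14 simulated meta-datasets) were chosen so that
Monte-Carlo error is small relative to the tolerances being asserted.

## Known limitations

* AUC tie handling is validated against this package's own enumeration
  oracle, not against any external scoring implementation's internal tie
  policy.
* The MAD calling rule is a thresholding heuristic, not a mixture model; it
  under-counts at high contamination (see the calibration note above) and
  its false-positive rate depends on the null score distribution's tail.
* The meta-analysis assumes independent datasets and normal within-dataset
  effect estimates; no small-k corrections (Knapp–Hartung) are applied.
* The plateau model fits one breakpoint; multi-phase trajectories and
  Bayesian changepoint uncertainty are out of scope.
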
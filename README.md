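# integrinclust

Probabilistic analysis of integrin cluster populations in fluorescence
images of adherent cells.

Cells adhere to the extracellular matrix (ECM) through micron-scale
clusters of integrin receptors — the cores of focal adhesions. The sizes,
shapes, and positions of these clusters are strongly heterogeneous within
and between cells, so comparing conditions by population *averages* buries
real effects in variance. This package implements the alternative:
describe each measured cluster property with a two-parameter probability
model and track experimental effects through the fitted parameters.

It is aimed at quantitative cell biologists and image analysts who have
cropped single-cell, two-channel (integrin + cytoskeleton) 8-bit images —
or who want a fully ground-truthed synthetic benchmark of such images —
and need per-cluster measurements and population-level fits per condition.

## The models

For each cluster the pipeline measures:

* **size** — pixel count × pixel calibration (µm²);
* **shape** — eccentricity of the *equivalent ellipse*, the ellipse with
  the same normalized second central moments as the cluster's pixels
  (each pixel contributing 1/12 per diagonal moment as a unit square):
  with moment-matrix eigenvalues λ₁ ≥ λ₂, e = √(1 − λ₂/λ₁), so 0 is a
  circle and values near 1 an elongated streak;
* **location** — two normalized radial metrics built from the ray through
  the cell centroid and the cluster centroid: the *edge distance*
  (d_ce − d_cc)/d_ce (0 at the periphery, 1 at the centroid) and the
  *center distance* d_cc/R̄, where R̄ is the mean centroid-to-edge
  distance over that cell's clusters.

Population models, each with parameters (α, β):

| property | model | fit | filter | mean |
|---|---|---|---|---|
| size | lognormal: ln x ~ N(α, β²) | maximum likelihood | ≥ 0.02 µm² | exp(α + β²/2), median exp(α) |
| edge distance | gamma (shape α, scale β) | histogram least squares | > 0.5 µm² | αβ |
| eccentricity | beta(α, β) | histogram least squares | ≥ 0.1 µm² | α/(α+β) |

The lognormal is the natural size model for nucleation-and-growth
processes (an exponential alternative is available through
`compare_models()`); gamma arises for edge distances as the waiting-time
distribution of Poisson cluster-formation events behind an advancing cell
edge; beta is the canonical model for a quantity confined to [0, 1].
Small clusters are excluded from the shape fit because a handful of
pixels admits only a few discrete eccentricity values, and clusters
≤ 0.5 µm² from the location fit, where no clear positional trend exists.
All fits report 95% confidence intervals (Fisher information for MLE,
Jacobian linearization for least squares).

## Worked example

Generate a ground-truthed two-condition synthetic dataset and run the
full pipeline (segmentation → per-cluster measurement → population fits):

```r
library(integrinclust)

conds <- list(
  "2 ug/mL"   = population_params(-1.1, 1.0, 8, 1.5, 2, 0.15, 150),
  "200 ug/mL" = population_params(-1.7, 0.8, 6, 1.8, 2, 0.09, 150))
dir <- file.path(tempdir(), "demo")
generate_condition_dataset(conds, n_cells = 5, dir, rng_seed = 42)
res <- run_pipeline(dir)

res$summaries$summary[, c("condition", "n_clusters", "size_alpha",
                          "size_median_um2", "loc_mean_edge_dist",
                          "shape_mean_ecc")]
#>   condition n_clusters size_alpha size_median_um2 loc_mean_edge_dist
#> 1   2 ug/mL        589 -0.9383871       0.3912584          0.3025376
#> 2 200 ug/mL        650 -1.6881286       0.1848652          0.1927876
#>   shape_mean_ecc
#> 1      0.8341743
#> 2      0.7807443
```

Reading the table: at the higher coating density the fitted lognormal
scale α and the median cluster size drop (clusters get smaller), the
gamma mean edge distance drops (clusters sit closer to the cell
periphery), and the beta mean eccentricity drops (clusters are rounder) —
the three signatures the population models are designed to expose.
Individual fits carry their uncertainty:

```r
res$summaries$size$fits[["2 ug/mL"]]
#> lognormal fit (mle, n = 589)
#>   alpha = -0.938387  [-1.04103, -0.835742]
#>   beta  = 1.27099  [1.20044, 1.34568]
#>   log-likelihood = -424.284
```

`run_pipeline(dir, out_dir = "...")` additionally writes
`cluster_records.csv`, `condition_summary.csv`, `size_shape_table.csv`
(the size-stratified eccentricity heatmap), per-condition fit JSONs, and
a run log.

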
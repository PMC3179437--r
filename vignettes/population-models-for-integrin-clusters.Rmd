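---
title: "Population models for integrin cluster size, shape, and location"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population models for integrin cluster size, shape, and location}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(integrinclust)
```

## Why distributions, not averages

Integrin clusters — the receptor aggregates at the core of focal
adhesions — are intrinsically heterogeneous: within one cell their areas
span two orders of magnitude, their shapes range from dots to streaks, and
their radial positions from the centroid to the very edge of the cell.
When a treatment (here: the coating density of an ECM ligand) shifts these
populations, the shift is visible in the *shape of the distribution* long
before a difference in means becomes statistically persuasive. This
package therefore measures every segmented cluster and fits two-parameter
probability models per condition; the fitted parameters, their 95%
confidence intervals, and the derived means/medians are the quantities
compared across conditions.

## The measurement pipeline

1. **Cell body** (`segment_cell_body`): threshold the per-pixel maximum of
   the integrin and cytoskeleton channels (Otsu by default), close with a
   disk structuring element, fill interior holes, keep the largest
   component. The result is a single filled region whose unweighted
   centroid, area, and angle-ordered boundary define the cell geometry.
   The channel fusion rule (maximum) reflects that cytoskeletal remnants
   and integrin signal jointly delineate the spread cell; the closing
   radius (default 5 px) must bridge gaps between stress-fiber remnants
   and is exposed in the configuration.
2. **Clusters** (`segment_clusters`): pixels of the integrin channel
   strictly above a threshold, labeled as connected components
   (8-connectivity by default — the convention under which "a 0.1 µm²
   cluster is 5 contiguous pixels" holds), filtered to a calibrated area
   of at least 0.02 µm². The filter is inclusive: a component of exactly
   0.02 µm² is kept, because what is excluded is anything *smaller*.
3. **Per-cluster metrics** (`measure_clusters`): area = pixel count ×
   calibration with no sub-pixel correction (size statements in this field
   are pixel-count statements); equivalent-ellipse eccentricity from the
   second central moments of the pixel coordinates with the +1/12
   unit-square variance on both diagonal moments (this makes a single
   pixel isotropic, eccentricity 0, and matches the classical
   `regionprops` definition); and the two radial location metrics below.

### Radial location metrics

Both metrics are built on one geometric construction: the ray from the
cell centroid through the cluster centroid. The implementation marches
along this ray in 0.25 px steps and takes the *last inside-mask sample
before the first exit* as the edge point, giving the centroid-to-cluster
distance d_cc and the centroid-to-edge distance d_ce. The first-exit rule
is a deliberate convention: on the star-convex synthetic cells there is
exactly one exit, and on irregular real masks the rule keeps the metric
single-valued and deterministic. The normalized edge distance
(d_ce − d_cc)/d_ce is 0 at the periphery and 1 at the centroid; a cluster
lying beyond its own ray's edge point (possible on real, non-convex
masks) is clamped to 0 and flagged. The normalized center distance
divides d_cc by the cell's average radius — the mean of d_ce over that
cell's clusters — and may legitimately exceed 1.

## The population models

| property | model | estimator | filter |
|---|---|---|---|
| area (µm²) | lognormal, ln x ~ N(α, β²) | closed-form MLE | ≥ 0.02 µm² |
| edge distance | gamma, shape α / scale β | histogram least squares | > 0.5 µm² |
| eccentricity | beta(α, β) | histogram least squares | ≥ 0.1 µm² |

*Lognormal for size*: cluster growth by many small multiplicative events
(nucleation and growth) produces lognormal size populations; the MLE is
closed-form (α = mean of ln x, β with the n denominator), so no optimizer
is involved, and an all-equal sample degenerates gracefully to β = 0 with
a flag. `compare_models()` scores the lognormal against the exponential
alternative (anisotropic-growth prediction) on a shared log-binned
histogram by sum of squared residuals.

*Gamma for edge distance*: if cluster nucleation events occur at the
advancing cell edge as a Poisson process, the distance between a cluster
and the present edge plays the role of a gamma-distributed waiting time;
α then counts formation events and β is the inverse event rate. The fit
is restricted to clusters larger than 0.5 µm² (strictly), where the
positional signal is clear. The mean αβ summarizes how peripheral the
large clusters sit.

*Beta for eccentricity*: eccentricity is confined to [0, 1] by
definition, and the beta family is the canonical two-parameter model on
the unit interval. Clusters below 0.1 µm² are excluded: with fewer than
5 pixels only a few discrete eccentricity values exist, and including
them would skew the distribution toward those quantized values. Exact 0
or 1 observations are nudged inward by 1e-9 before likelihood evaluation
because the density is unbounded or zero at the endpoints.

### Estimation details

*Maximum likelihood*: lognormal and exponential closed-form; gamma and
beta by BFGS on the log-likelihood in log-parameter space (positivity by
construction) from method-of-moments starts, which are deterministic and
land close to the optimum for these families. Standard errors come from
the observed Fisher information; intervals are Wald, computed on the log
scale for positivity-constrained parameters so lower bounds stay
positive.

*Histogram least squares*: the empirical frequency distribution is a
density-normalized histogram (counts / (n × bin width)), so the fit is
invariant to sample size; defaults are 30 log-spaced bins for sizes
(size distributions are inspected on logarithmic axes) and 25 linear bins
on [0, 1] for eccentricity and location. Parameters minimize the sum of
squared differences between bin densities and the model density at bin
centers, by Levenberg–Marquardt (`minpack.lm`), again from
method-of-moments starts. Confidence intervals use the linearized
covariance σ̂²(JᵀJ)⁻¹ with a central-difference Jacobian at the optimum.
The bin counts are a design choice, not a data-derived quantity; both are
exposed through `bin_spec()`. Fits require at least 50 observations (or
5 non-empty bins when fitting a pre-built histogram); per-size-bin shape
fits in `shape_by_size` go through the histogram path with a lower
per-bin minimum of 30, since the histogram is already in hand.

Asymptotic (Fisher/Jacobian) intervals were chosen over bootstrap
because they are deterministic, fast, and testable against coverage in
simulation; at the sample sizes of interest (thousands of clusters per
condition) the difference is immaterial.

## The synthetic-data generator

The generator exists so that every stage — segmentation, metrics,
fitting, trend detection — can be validated against known truth without
any experimental data.

* **Cell shape**: a star-convex radial-harmonic perturbation of a disk
  (harmonics k = 2..5 with decaying amplitudes, normalized so the
  roughness parameter is the exact relative amplitude). Star convexity
  guarantees the centroid-to-edge ray construction is single-valued.
  Default geometry: 512 × 512 px images with mean cell radius 160 px.
  At the default calibration of 0.02 µm²/px (≈ 0.141 µm/px) this is a
  ~45 µm spread cell, the physical size of a well-spread fibroblastic
  cell, and it holds 150 clusters per cell at a realistic ~3% area
  fraction.
* **Cluster populations** (`population_params`): areas lognormal,
  eccentricities beta, edge distances gamma truncated to [0, 1) by
  resampling (the measured quantity is a normalized fraction; the
  truncation correction is negligible for the means used here, e.g.
  P(x ≥ 1) ≈ 5e-4 at gamma(2, 0.12)). A Gaussian copula couples size
  rank to eccentricity rank with coefficient `size_ecc_coupling`
  without touching either marginal; 0.5 is used as the working value in
  the acceptance analyses — strong enough that size-stratified shape
  fits must detect it, weak enough that the per-size-bin eccentricity
  distributions still overlap broadly, as they do in real adhesion data.
* **Rendering** (`render_image`): each cluster is an anisotropic
  Gaussian-profile ellipse, amplitude 255 × 2^(−ρ²) in the normalized
  elliptical radius ρ, so the half-maximum contour encloses exactly the
  true area. Thresholding at half the peak amplitude (127) therefore
  recovers the true footprint, while any other threshold yields
  systematically smaller or larger footprints — the threshold dependence
  real immunofluorescence spots show. Background is Gaussian noise of
  standard deviation 255/snr, quantized to 8 bits; the cytoskeleton
  channel is a dim uniform fill of the cell mask. The default cluster
  threshold in `default_config()` is this half-maximum value; for real
  images an Otsu or per-image manual override is the right choice.
* **Ground truth**: per-cluster true area, eccentricity, edge distance,
  center coordinates, and an `overlaps` flag. The flag is operational:
  a cluster is marked when its elliptical core intersects another's or
  when several clusters' noiseless half-maximum footprints form one
  connected component (tail bridging). Flagged clusters cannot be
  separated by any thresholding segmentation — resolving them is out of
  scope — so recovery statistics are reported on the separable subset.
  At the default density about 15–30% of clusters are flagged, which is
  also why whole-population fits on segmented (rather than true) areas
  carry a small upward size bias (≈ +0.1 on the lognormal α at full
  scale): merged neighbors masquerade as single larger clusters.
* **Determinism**: one integer seed per dataset; per-cell substream
  seeds are derived arithmetically and recorded in the manifest, so
  every TIFF and truth CSV regenerates bit-identically.

What the generator does *not* emulate: photophysics (bleaching, a real
point-spread function), 3-D structure, intensity variation within and
between clusters, cluster-overlap structure with biological correlation,
or touching cells. Passing tests on synthetic data therefore validate
the measurement and inference machinery — they do not certify
segmentation quality on real micrographs, where threshold selection
remains the user's scientific decision (the per-image override exists
for exactly this reason).

## Choices where the design was genuinely open

* **Pixel calibration**: pixel-count statements for small clusters are
  mutually consistent only approximately (a 0.02 µm² exclusion phrased
  as "fewer than two pixels" implies ~0.01 µm²/px; "0.1 µm² is fewer
  than 5 pixels" implies 0.02 µm²/px). The package fixes no calibration:
  `pixel_area_um2` is a required parameter everywhere, with 0.02 µm²/px
  as the documented default.
* **Filter boundary semantics**: size analysis keeps ≥ 0.02 µm²
  (inclusive); shape analysis keeps ≥ 0.1 µm² (what is excluded is
  "smaller than 0.1"); location analysis keeps > 0.5 µm² (strictly
  "larger than"). The size–shape table bins are left-closed, right-open,
  {0.1, 0.2, 0.3, 0.4, 0.6, 1.0} µm², with clusters ≥ 1.0 µm² excluded.
* **Pooling**: fits pool clusters across all cells of a condition rather
  than fitting per cell and averaging — the condition-level population
  (thousands of clusters) is the modeled object.
* **Condition ordering**: by the numeric concentration parsed from the
  label, so trend tables are well-defined.
* **Cluster counts per cell** are reported as a diagnostic
  (`clusters_per_cell`) but no directional claim is attached to them.

## Problem sizes used in the tests

Estimator calibration runs 200 Monte-Carlo replicates at n = 5,000 per
family (the per-condition scale of the motivating experiments:
at least 35 cells and 5,000 clusters per condition). The end-to-end
trend test renders 3 conditions × 10 cells × 150 clusters; the
acceptance script runs the full 3 × 35-cell scale. Oracle-equivalence
tests use 200 random pixel blobs (eccentricity) and 50 random 64 × 64
masks × both connectivities (labeling).

## Known limitations

* Overlapping clusters are flagged, not split; population fits on dense
  fields inherit a small size-inflation bias from unresolved merges.
* The least-squares intervals treat bin residuals as independent and
  homoscedastic; they are approximate (their simulation coverage is
  nevertheless within the 90–99% band at the tested sample sizes).
* The edge-distance metric follows the centroid ray, not the nearest
  boundary point; on strongly non-convex real cells the two differ, and
  the ray convention is the one implemented throughout.
* Real-image thresholds are not estimated from biology: Otsu is a
  reproducible default, and the per-image override mirrors manual
  selection.
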
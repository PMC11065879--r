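---
title: "Phenology-based training-sample migration for soybean mapping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-based training-sample migration for soybean mapping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomigrate)
```

## The problem

Supervised crop-type mapping needs labelled training points for every
region and year mapped, but ground surveys are expensive and rarely cover
the full space-time extent of a mapping campaign. `phenomigrate`
implements a sample-*migration* strategy: a modest set of surveyed soybean
points from one region-year is used to label, automatically, a large pool
of anonymous cropland points elsewhere — turning one survey into training
data for many maps. The package covers the whole desk workflow around that
idea: spectral/SAR feature computation, temporal regularization, phenology
extraction, the migration fit itself, random-forest classification,
post-processing and validation, plus a synthetic scene generator that
makes each stage testable with known truth.

## Models and procedure

### Temporal regularization

Optical observations arrive irregularly (5-day revisit thinned by cloud).
All per-sample curves are composited to a fixed grid of 10-day bins
spanning the growing season, day of year 90–318, giving 23 bin centres at
DOY 95, 105, …, 315 (`temporal_grid()`). Per-bin medians absorb duplicate
observations; empty bins are filled with the quadratic Newton
divided-difference interpolant through the three nearest observed bins,
which is exact for any underlying polynomial of degree ≤ 2; the filled
series is then smoothed with a Savitzky–Golay filter (window 7 bins,
order 2 by default; the filter reproduces degree-≤2 polynomials exactly,
including at the edges, where fits on the truncated end windows are used).
Bands are smoothed first and indices derived from the smoothed bands; the
reverse order is available via `smooth_before_indices = FALSE`, and on our
synthetic scenes the two orderings give practically identical decisions.

### Phenology

The peak of season (POS) is the bin centre of the EVI maximum (earliest
bin on ties). SOS and EOS follow the amplitude-median rule: the level
`min + 0.5 (max − min)` is computed from the global extremes over the grid
window, SOS is the last upward crossing of that level before POS and EOS
the first downward crossing after it, both linearly interpolated between
bin centres, clamped to the grid limits when a crossing does not exist.
Curves with amplitude below 10⁻⁶ are rejected as having no seasonal
signal. The global-minimum amplitude base (rather than separate pre- and
post-season minima) was chosen for determinism; on single-peak seasonal
curves the two coincide. A caveat worth knowing: on crop curves with a
long flat plateau, the *peak date* is intrinsically weakly identified —
mid-amplitude crossings are sharp features and are recovered to within one
bin, but the plateau argmax can legitimately move by a bin or two under
resampling. Nothing downstream depends delicately on POS: it enters only
through the CCI evaluation and the biomass-integral split point.

### Screening: the Concave-Convexity Index

OSAVI tracks canopy development while TCARI reacts to chlorophyll
absorption; their ratio falls as canopy chlorophyll accumulates. In
high-chlorophyll crops (soybean, corn, rice) pigment dynamics saturate
early, so the TCARI/OSAVI curve dips mid-season — it is *concave*; in
low-chlorophyll cash crops (peanut, cotton, potato) it is convex. With
`r(·)` the gridded ratio curve interpolated at the phenological dates,

$$\mathrm{CCI} = 2\,r(\mathrm{POS}) - \left[ r(\mathrm{SOS}) + r(\mathrm{EOS}) \right],$$

and `CCI < 0` marks a potential soybean point, `CCI ≥ 0` a potential
non-soybean point. OSAVI is computed as printed in its source table, with
SWIR1 in the denominator, `1.16(ρ_NIR − ρ_red)/(ρ_NIR + ρ_SWIR1 + 0.16)`;
because the literature-standard form uses the red band there, a
`osavi_standard` flag substitutes it. The default follows the printed
form so results are comparable with the original protocol; the screening
logic is unaffected because only the curve's shape, not its level, enters
the CCI. Any index denominator smaller than 10⁻⁹ in absolute value yields
a missing value rather than ±Inf.

### Confirmation: two trivariate Gaussians on curve integrals

Six growing-season integrals (trapezoidal, over the sample's own
[SOS, EOS], in index-units × days) summarize each sample: a high-value
group (∫EVI, ∫RE2, ∫SWIR2), where soybean runs high, and a low-value
group (∫LSWI, ∫RENDVI, ∫REPI), where it runs low. Each group's reference
integrals are modelled as N(μ, Σ) with the sample mean and covariance; a
ridge `λ · tr(Σ)/3 · I` with λ = 10⁻⁶ is added when the condition number
exceeds 10⁸ (small surveys can have nearly collinear integrals). At least
30 reference points are required — below that a 3-D covariance is too
uncertain to set percentile thresholds, and the fit aborts with guidance
rather than degrade silently.

The admission thresholds derive from the central 50%-probability region of
the fitted Gaussian. Its bounding density p₅₀ is estimated by Monte Carlo
(median density of 10⁵ seeded draws from the fitted model); since density
is monotone in Mahalanobis distance, p₅₀ corresponds to the radius
r₅₀ = √(χ²₃ median) ≈ 1.538, which is the closed form used as an
independent oracle in the tests (the Monte-Carlo route stays the
documented method and the two agree within a fraction of a percent at
10⁵ draws). Reference points denser than p₅₀ are the *robust* exemplars.
Then, per group,

* soybean admission threshold: 90th percentile of the robust points'
  Mahalanobis distances (≤ r₅₀ by construction);
* non-soybean rejection threshold: 95th percentile of *all* reference
  distances.

A candidate is **soybean** iff CCI < 0 and both distances fall below the
respective admission thresholds; **non-soybean** iff both distances exceed
the respective rejection thresholds (CCI does not enter this rule, which
is applied exactly as stated in the original decision criteria); anything
between is discarded. Because admission ≤ r₅₀ < rejection, the two label
sets are disjoint. The design deliberately trades recall for purity: on
the default synthetic scene roughly a third of true soybean candidates are
admitted, but essentially every admitted point is a true soybean. The
rejection-threshold sentence for the low group is truncated in the source
protocol; it is implemented symmetrically with the high group (95th
percentile), which is the only reading consistent with the two-group
decision rule. Mahalanobis distances are computed through the Cholesky
factor of Σ, never an explicit inverse.

When surveys exist for several region-years, `select_reference_set()`
picks the source set by the migration priority: same region (temporal
migration, nearest year first), else same year in the climatically nearest
region (spatial), else nearest year then nearest climate zone
(spatiotemporal); ties break by smaller year gap, then lexicographic
region id.

### Features and classification

Per sample, 69 optical features: six statistics (min, max, std, 15/50/90th
percentiles — linear-interpolation definition) for each of five indices
(EVI, GCVI, LSWI, REPI, NDPI) and five bands (RE1–3, SWIR1–2); SOS, EOS,
LOS; amplitude and phase of the first two harmonics of a least-squares fit
`a + bt + Σₘ [Cₘcos(2πmωt) + Dₘsin(2πmωt)]` with ω = 1/365 on the raw
valid EVI observations; and the two accumulated-biomass integrals ∫EVI
over [SOS, POS] and [POS, EOS]. The harmonic block is read as two
harmonics × (amplitude, phase), and the biomass block as the two
phenophase integrals — the feature manifest in the output makes the chosen
inventory explicit wherever totals could be counted differently. Per
sample, 50 SAR features: seven statistics for each of the five parameters
(VH, VV, cross-ratio, cross-sum, RVI = 4σVH/(σVH+σVV), channel
combinations computed in linear power after 10^(dB/10) conversion — sums
and ratios of decibel values are not physically meaningful, though a
dB-domain variant exists for sensitivity checks) plus three temporal
principal-component scores per parameter (eigenvector signs fixed by
making the largest-magnitude loading positive, so scores are
reproducible).

Classification follows a fixed protocol: stratified 50/50 split per
region; top-50% feature selection by seeded random-forest impurity
importance; forests fitted at every tree count 50–500 in steps of 50 with
seed 999; the count chosen as the smallest above 100 that is a local
maximum of held-out accuracy (the accuracy curve is measured on the 50%
test split, a choice the protocol leaves open); the final forest refitted
at that count. Predictions with any missing feature become nodata. The
binary map is cleaned by one pass of an eight-neighbourhood majority
filter (3×3 vote including the centre; ties keep the centre; nodata
neighbours excluded), which removes single-pixel speckle and fills
single-pixel holes while leaving homogeneous areas and straight boundaries
untouched.

### Validation

Producer's accuracy (recall), user's accuracy (precision), F1, overall
accuracy and Cohen's kappa from the soybean-positive confusion matrix;
zero-denominator metrics are reported as `NA` and named, never silent.
The source protocol prints PA and UA with swapped denominators relative to
the remote-sensing convention; both conventions are computable
(`convention = "swapped"`) and the output records which was used. Area
agreement uses the squared Pearson correlation for R² (so a constant bias
shows up in RMSE/MAE, not R²), with geodesic per-pixel areas on WGS84 when
the map is in degrees.

## The synthetic generator

Every archetype parameter lives in `inst/extdata/archetypes.yaml`. Band
trajectories follow `base + (peak − base) · g(t)^e`, with `g` a normalized
double logistic (green-up and senescence midpoints and rates per crop) and
`e` the chlorophyll-dynamics exponent applied to the pigment-sensitive
bands (red, RE1): `e < 1` (high-chlorophyll crops, 0.35) makes pigment
absorption saturate before canopy structure — producing the concave
TCARI/OSAVI curve — and `e > 1` (low-chlorophyll crops, 2.5) delays it,
producing the convex one. Peak-reflectance vectors were chosen as
plausible canopy values that realize the documented orderings: soybean
exceeds corn in ∫EVI, ∫RE2, ∫SWIR2 and runs below it in ∫LSWI, ∫RENDVI,
∫REPI, and zero-noise CCI is negative for soybean/corn/rice and positive
for peanut/cotton/potato. Observations run at a 5-day cadence (SAR:
12-day) thinned by a 20% cloud-gap probability, with Gaussian band noise
(σ = 0.012) and per-point jitter of season timing (σ = 3 days) and canopy
vigor (5% log-scale). The default scene is 200 candidates for each of
soybean, corn, rice and peanut plus 100 reference soybean points. A
`separation` dial pulls every non-soybean archetype toward soybean's
parameters for effect-size sweeps; label error grows monotonically as it
shrinks.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mixed pixels and intercropping, double-cropping
(two-peak seasons), spatially correlated noise and cloud runs, atmospheric
residuals, SAR speckle with its non-Gaussian statistics, and registration
error between optical and SAR. Real-scene accuracies will be lower than
the synthetic ones; the synthetic scene demonstrates correctness of the
machinery, not expected operational accuracy.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics throughout.
* Integrals: trapezoidal with linear interpolation at fractional
  endpoints — exact on piecewise-linear curves, deterministic.
* Ties: earliest bin for the EVI maximum; centre value for majority-filter
  ties; feature-importance ties break by name.
* Degenerate inputs: flat EVI curves, fewer than three observed bins,
  fewer than 30 references, single-class labels, rank-deficient harmonic
  designs and non-finite integrals all raise immediate, named errors.
* All randomness (Monte-Carlo draws, splits, forests, scene simulation)
  flows through explicit seeds recorded in the run manifest together with
  a hash of the full configuration.

## Problem sizes

The shipped tests and the acceptance script run the default scene (800
candidates + 100 references), 10⁴-point Gaussian-oracle fits with 10⁵
Monte-Carlo draws, and 100×100 rasters — sizes at which every stage's
behaviour is already asymptotic enough for the checks involved while the
whole suite stays interactive on one core.

## Known limitations

Single-peak phenology only; thresholds are never shared across
region-years (by design, each migration is locally calibrated); the
migration's recall depends on how tight the reference survey's integral
distribution is — small, homogeneous surveys admit fewer candidates; and
the CCI screen assumes the high/low-chlorophyll dichotomy holds for the
crop mix at hand (a region dominated by, say, sunflower behaves like the
convex group, but a crop with intermediate chlorophyll dynamics will
land near CCI ≈ 0, where the screen is least informative).
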
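# phenomigrate

Soybean mapping from satellite image time series without new field
campaigns. `phenomigrate` generates soybean / non-soybean training samples
by *migrating* a small set of reference soybean points across years and
regions, then runs the surrounding mapping workflow: feature extraction,
random-forest classification, post-processing and validation. It is aimed
at crop-mapping practitioners who have dense optical (Sentinel-2-like) and
dual-polarization SAR (Sentinel-1-like) time series but only sparse,
unevenly distributed ground surveys.

## The method

Candidate cropland points are screened in two stages:

1. **Chlorophyll concavity.** Crops with high canopy chlorophyll (soybean,
   corn, rice) trace a *concave* TCARI/OSAVI curve through the season;
   low-chlorophyll cash crops (peanut, cotton, potato) trace a convex one.
   With phenological dates from the EVI curve (POS at the curve peak,
   SOS/EOS by the amplitude-median rule), the Concave-Convexity Index

   CCI = 2 · r(POS) − [ r(SOS) + r(EOS) ],   r = TCARI / OSAVI

   flags `CCI < 0` points as potential soybean.

2. **Gaussian confirmation.** For the reference soybean points, six
   growing-season curve integrals over [SOS, EOS] are collected into a
   high-value group **x**ₕ = (∫EVI, ∫RE2, ∫SWIR2) and a low-value group
   **x**ₗ = (∫LSWI, ∫RENDVI, ∫REPI), each assumed trivariate Gaussian
   N(μ, Σ). The density level p₅₀ bounding the central 50%-probability
   region is estimated by Monte Carlo; reference points denser than p₅₀
   are "robust" exemplars. With Mahalanobis distance
   D(x) = √((x−μ)ᵀ Σ⁻¹ (x−μ)), a candidate is admitted as **soybean** iff
   CCI < 0 and both distances fall below the 90th percentile of the robust
   points' distances, and as **non-soybean** iff both distances exceed the
   95th percentile of all reference distances. Everything else is
   discarded.

The generated labels train a seeded random forest (tree count selected as
the first local accuracy maximum above 100 trees, seed 999, stratified
50/50 split, top-50% feature selection) on 69 optical features (index and
band statistics, phenology, EVI harmonics, accumulated biomass) and 50 SAR
features (statistics plus temporal principal components). Maps are cleaned
with an eight-neighbourhood majority filter and validated with
producer's/user's accuracy, F1, overall accuracy, Cohen's kappa and
mapped-vs-reported area agreement (R², RMSE, MAE).

A synthetic multi-crop scene generator (documented archetypes for soybean,
corn, rice, peanut, cotton, potato) makes every stage testable at desk
scale with known truth.

## Worked example

```r
library(phenomigrate)

scene <- simulate_region(seed = 1)          # 4 crops x 200 + 100 references
cfg   <- pipeline_config(seed = 1)
mig   <- migrate_samples(scene$reference, scene$candidates, cfg)
mig
#> <soy_migration> fitted on 100 reference soybean points
#>   candidates: 800 | soybean: 61 | non-soybean: 602 | discarded: 137

coef(mig)$high[c("r50", "soy_thresh", "nonsoy_thresh")]
#>           r50    soy_thresh nonsoy_thresh
#>      1.537020      1.463376      2.900820

# precision of the generated labels against generator truth
lab <- mig$labels
mean(scene$truth[lab$id[lab$label == "soybean"]] == "soybean")
#> [1] 1
```

All 61 points labelled soybean are true soybeans; the discarded points are
candidates that fell between the admission and rejection thresholds, which
is the intended behaviour — the method trades recall for label purity.
The full pipeline (`run_pipeline(cfg)`) continues through feature
extraction, random-forest training and majority filtering, reaching 100%
held-out overall accuracy against generator truth on this well-separated
default scene.

A thin command-line wrapper is installed at `inst/cli/phenomigrate.R` with
verbs `run`, `simulate`, `migrate` and `validate`.

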
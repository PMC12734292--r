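# respiromics

Quantitative assessment of respiratory-muscle sarcopenia from unenhanced
chest CT, and validation of simplified slice-sampling segmentation
protocols.

Whole-volume manual segmentation of the pectoralis major (PM), pectoralis
minor (Pm), serratus anterior (SA), and fourth intercostal (4I) muscles
yields rich density and radiomic biomarkers of sarcopenia, but takes days
per patient. This package implements, as a reusable and tested pipeline,
the protocol for replacing whole-muscle segmentation with small
landmark-anchored slice sets:

* **Slice stacks and exclusion rules** — per-slice summaries along each
  muscle's segmentation plane (axial for PM/Pm, coronal for SA/4I);
  removal of slices with fewer than 20% of the maximum slice's pixels, then
  of per-subject mean-density outliers beyond ±3 z.
* **Radiomics** — an IBSI-style extractor (104 features: first-order,
  shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM; fixed 25 HU bins) with mean
  density in Hounsfield units always pooled over the included voxels.
* **Jensen–Shannon slice profiling** — each slice's density histogram vs
  the whole-muscle histogram, `JS = sqrt(½KL(p‖m) + ½KL(q‖m))` with base-2
  logs (`m = (p+q)/2`), bounded in [0, 1]; a data-driven landmark is the
  minimizer of a rolling median of the profile in the central half of the
  muscle.
* **Slice-set protocol** — 1S/3S/5S/7S sets sampled symmetrically around
  the landmark with five slices interposed (stride 6), re-sampled at
  landmark offsets −2…+2; deviations from whole-muscle values scored as
  MAE (HU) for density/SD and MAPE (%) for radiomic features, compared
  across set sizes with a Shapiro-routed ANOVA/Kruskal–Wallis battery,
  Dunn–Holm post hocs, and Friedman effect sizes (Kendall's W, Cohen's
  f = √(W/(1−W))).
* **Biomarker selection** — feature cleaning (missing/zero-variance/
  |r| > 0.9 pruning), LASSO-penalized logistic selection (10-fold CV
  deviance minimizer), AIC backward stepwise refinement with Wald p < 0.05,
  standardized group deltas, and a logistic cluster model contrasting
  variability-related (texture-matrix) against structural-related
  (first-order/shape/density) scores.
* **Synthetic cohort generator** — CT-like muscle volumes plus aligned
  masks (NIfTI), calibrated so group densities, age trends, slice counts,
  peripheral-slice heterogeneity, and sarcopenic texture contrasts match
  the published cohort-level statistics; it is the test bed for the whole
  pipeline, since the underlying clinical CTs are not distributable.

## Worked example

```r
library(respiromics)

cfg <- pipeline_config(
  cohort = cohort_config(n_subjects = 30, sarcopenic_fraction = 17/30, seed = 1L),
  feature_mode = "density", seed = 1L)
res <- run_pipeline(cfg, out_dir = "run1")

subset(density_mae(res), muscle == "PM")
#>    muscle set_size   mae_hu
#> 3      PM       1S 3.364766
#> 7      PM       3S 2.555733
#> 11     PM       5S 2.421277
#> 15     PM       7S 2.305762

res$density_stats$group_tests[, c("muscle", "mean_sarcopenic", "mean_non_sarcopenic", "p")]
#>   muscle mean_sarcopenic mean_non_sarcopenic            p
#> 1     PM      12.0409384            36.35952 0.0002383977
#> 2     Pm      21.1962595            30.59068 0.1182900533
#> 3     SA      -0.1476021            23.84222 0.0037192052
#> 4     4I     -37.2828182           -13.95899 0.0103417041
```

The first table is the protocol's headline metric: the mean absolute error
(HU) of slice-set mean density against the whole-muscle reference,
averaged over 30 subjects and all five landmark offsets — a single slice
already approximates PM whole-muscle density to ~3.4 HU, errors shrink as
more slices are sampled, and every muscle and set size stays under the
6 HU bound. The second table shows the simulated sarcopenic group reading
lower density in all four muscles, as calibrated; at n = 30 the smallest
contrast (Pm, a 9 HU group gap against ~15 HU subject SDs) is directional
but not always significant at a given seed.

For the full radiomic analysis (feature vectors, set-size MAPE
comparisons, biomarker selection and cluster odds ratios) use
`feature_mode = "full"`. A thin CLI wraps the same functions:

```sh
exec/respiromics simulate --out cohort_dir --seed 7      # NIfTI bundle + manifest
exec/respiromics run --out run_dir --seed 7 --features density
```

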
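---
title: "Respiratory-muscle CT radiomics: models, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-muscle CT radiomics: models, protocol, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respiromics)
```

## The problem

Respiratory-muscle sarcopenia — loss of mass and quality in the pectoralis
major (PM), pectoralis minor (Pm), serratus anterior (SA), and intercostal
(4I) muscles — worsens outcomes in chronic lung disease. Unenhanced chest CT
can quantify it: muscle attenuation in Hounsfield units (HU) falls as fat
infiltrates muscle (muscle reads roughly 30–50 HU, adipose tissue about
−100 HU), and radiomic texture features capture the micro-architectural
changes that mean density misses. Whole-muscle manual segmentation is far
too slow for practice, so the protocol implemented here asks two questions:

1. Which radiomic features of whole muscle volumes discriminate sarcopenic
   from non-sarcopenic subjects?
2. How little segmentation suffices? Specifically, how well do 1, 3, 5, or 7
   slices (1S/3S/5S/7S), sampled symmetrically around a landmark with five
   slices interposed (stride 6), approximate whole-muscle density and
   radiomics, and how robust is that to the landmark being misplaced by one
   or two slices?

Because the underlying clinical CTs are not distributable, the package
includes a first-class synthetic cohort generator whose statistical
structure reproduces the published cohort-level anchors, and the entire
pipeline is exercised end-to-end on that synthetic cohort.

## The synthetic cohort model

Each muscle volume is a stack of end-tapered elliptical cross-sections
(taper: sine profile falling to 0.42 of the peak radius, so end slices hold
roughly 18% of the peak pixel count and the 20%-of-maximum pixel filter
trims one or two of them). Voxels follow a two-component mixture:

* a **muscle component** `N(mu_muscle, sigma_within)` with in-plane
  spatially correlated noise (box-smoothed white field, correlation length
  `texture_corr_len` voxels), and
* a **fat component** `N(-100, 20)` HU, entered with per-voxel probability
  `fat_fraction`, assigned independently per voxel (fine marbling). The thin
  4I muscle instead uses continuous partial-volume fat fractions
  (`fat_fraction ± 0.15`, uniform), reflecting its few-pixel cross-sections
  where every voxel mixes muscle, fat, and adjacent tissue.

Three deterministic axial profiles shape the heterogeneity that the
protocol exploits:

* **Peripheral fat ramp** (`edge_fat_boost`): fat probability rises linearly
  over the first/last 15% of slices, uncompensated, emulating
  partial-volume contamination at the muscle ends. This is what the slice
  filters and the peripheral Jensen–Shannon elevation react to.
* **Axial density gradient** (`axial_gradient`, default 40 HU): slice mean
  density shifts by `40·q`, where `q ∈ [−1, 1]` is the signed distance from
  the landmark. Because the shift is antisymmetric about the landmark, the
  pooled whole-muscle histogram stays centred on the landmark slice's
  distribution — the Jensen–Shannon profile therefore attains its minimum at
  the landmark — while the area-weighted whole-muscle mean is essentially
  unchanged, keeping slice-set density errors small. An earlier design that
  instead increased fat fraction away from the landmark (mean-compensated)
  was abandoned: the slice minimizing divergence from the pooled histogram
  is then the slice whose fat fraction matches the cohort *average*, not the
  landmark.
* **Belly broadening** (`belly_sigma_boost`): the muscle-lobe SD doubles in
  a narrow Gaussian window (width 0.15 in `q`) at the landmark, so the
  landmark slice's histogram is the best single-slice surrogate of the
  pooled mixture. This encodes the premise of landmark-anchored sampling —
  the landmark sits where one slice best represents the muscle — and gives
  the JS profile a sharp, reliably localizable minimum.

**Calibration.** Group-level anchors are the published cohort values:
whole-muscle mean ± SD per muscle and sarcopenia group (e.g. PM 15.2 ± 18.8
HU sarcopenic vs 36.9 ± 14.1 HU non-sarcopenic; 4I −38.8 ± 23.0 vs −18.4 ±
25.3), age distributions 70.4 ± 12.5 vs 56.1 ± 20.0 years (truncated at 18),
BMI 22.0 ± 2.9 vs 24.9 ± 3.2 kg/m², sex composition 11/17 vs 5/13 female,
and mean slice counts 94/61/126/170 for PM/Pm/SA/4I. Each subject draws an
age, a fat fraction (`fat_subject_sd = 0.04` around the group default), and
a whole-muscle density target composed of the group anchor, a muscle-specific
age slope (−0.5 to −1.0 HU/year, matching the published age-group tables),
and a residual sized so the group SD matches its anchor. `calibrate_mu()`
then solves for `mu_muscle` such that the *expected post-filter* whole-muscle
mean equals the target — it models the taper geometry, the fat profiles, and
even the ±3 z-score slice exclusion analytically, so simulated group means
land on the anchors without empirical tuning. Age-linked density decline also
makes the age–sarcopenia association positive (Spearman ρ ≈ 0.7 at n = 30).

The sarcopenic group differs by: lower density targets, higher fat fraction
(texture contrast; subject-level fat variation makes texture features vary
continuously so group overlap is realistic), and a slightly longer texture
correlation length (coarser fatty marbling).

**What the generator does not emulate:** anatomy (no real muscle shapes,
ribs, or neighbouring organs), scanner physics (no beam hardening, dose
noise models, or reconstruction kernels), segmentation error beyond the
peripheral fat ramp, and longitudinal change. Passing tests therefore show
that the *pipeline machinery* is correct and that the protocol behaves as
described under the published cohort statistics — not that the biomarkers
would transfer to any particular clinical population.

**Problem sizes.** Default cross-sections are kept compact (PM ellipse
semi-axes 18 × 11 voxels ≈ 620 pixels per central slice at 0.7 × 0.7 mm
in-plane, 2 mm slices; 4I ≈ 25 pixels) — large enough for stable slice
histograms and texture matrices, small enough that a full 30-subject,
4-muscle cohort generates in a few seconds and the complete density
protocol runs in well under a minute. In-plane voxel spacing is not reported
for the source cohort; 0.7 mm is a typical chest-CT value and is recorded in
every manifest. Tests that need radiomic feature matrices over many seeds
use reduced cohorts (e.g. 14 subjects, 50-slice muscles); the statistical
properties asserted are size-stable.

## Slice stacks and exclusion rules

PM and Pm are stacked axially, SA and 4I coronally. Per slice the stack
records pixel count, mean and SD (sample, n−1) of masked HU. Two filters
apply, in order and scoped per muscle:

1. drop slices with pixel count strictly below 20% of the muscle's maximum
   slice;
2. compute z-scores of per-slice mean HU over the survivors and drop
   |z| > 3.

Running the pixel rule first stops tiny partial-volume slices from
distorting the mean/SD the z-rule uses. Filtering is idempotent and never
reorders slices. Whether the original analysis used population or sample SD
for the z-rule is not stated; sample SD is used here.

## Radiomic features

Features follow IBSI-consistent definitions. Intensities are discretized
with a fixed bin width of 25 HU anchored at the region minimum
(`level = floor((v − min)/25) + 1`) — the conventional CT radiomics default,
recorded in the manifest since the source analysis does not state its
settings. The vector (104 features) covers first-order statistics
(moment-based, population moments; robust MAD over the [P10, P90]
restriction), shape (voxel volume; surface area from exposed voxel faces
corrected by the isotropic 3/2 factor, hence sphericity; principal-axis
elongation/flatness; maximum diameter), and the five texture families:

* GLCM: symmetric, distance 1, features computed per direction (4 in 2D, 13
  in 3D) and averaged;
* GLRLM: run matrices over the same directions, averaged;
* GLSZM: zones by full connectivity (8-connected 2D, 26-connected 3D);
* GLDM: dependence threshold α = 0, dependence size = dependent neighbours + 1;
* NGTDM: distance-1 neighbourhood means.

Masked-out neighbours are excluded from every counting. Degenerate regions
(single gray level, single voxel) yield `NA` sentinels carried in a
`flagged` attribute — never silent zeros — and flagged values are excluded
from downstream percentage-error aggregation. The whole test suite checks
every matrix against a brute-force enumerator on random small instances,
and the named features against an independent naive-formula route.

Whole-muscle vectors use `whole_3d` mode. Slice-set vectors use
`per_slice_2d`: per-slice 2D features averaged across the set's slices,
because sampled slices are six apart and 3D texture across them would be
physically meaningless. Mean density is always pooled over the included
masked voxels (the protocol's density error is defined in HU over the
sampled voxels). A consequence worth noting: pooled SD over n voxels is not
the average of per-slice SDs, so `density_sd` of a stack of identical
slices differs slightly from the single-slice value (sample-SD n effects).

## Jensen–Shannon profiling and the sampling protocol

Each retained slice's histogram (5 HU bins over [−200, 200] HU, shared
across the muscle's slices; fine enough to resolve the fat/muscle
bimodality, coarse enough for small slices) is compared with the pooled
whole-muscle histogram via the Jensen–Shannon distance — the square root of
the symmetrized KL divergence with base-2 logarithms, so it is a metric
bounded in [0, 1]. Values outside the range clip into the end bins.

The landmark is either supplied (`fixed`, mirroring anatomical landmarks
such as the sternoclavicular joint for PM/Pm and the first costovertebral
joint for SA/4I) or selected data-driven (`auto`): the retained slice
minimizing a rolling median (window 5) of the JS distance within the
central 50% of retained slices, ties broken toward the midpoint. On default
synthetic muscles the auto landmark recovers the generator's ground truth
within ±2 slices for PM, Pm, and SA; 4I, with ~25-pixel cross-sections, is
noisier (within ~±10), which mirrors its reported segmentation fragility.

Slice sets of sizes 1/3/5/7 sample symmetrically around
`landmark + offset` with stride 6 and offsets −2…+2 (20 sets per muscle).
Any resolved index outside the retained slices is a hard boundary error
naming the set — callers must shrink the stride explicitly rather than get
silently truncated sets.

## Deviation metrics and statistics

Against the whole-muscle reference, density and SD deviations are absolute
differences in HU; radiomic deviations are absolute percentage errors
(MAPE), with references below epsilon flagged out rather than divided by.
Aggregates are means over subjects and offsets per muscle, feature, and set
size; a per-feature min–max normalization across set sizes supports the
usual normalized-MAPE displays.

The comparison battery routes through Shapiro–Wilk on pooled within-group
residuals at α = 0.05 to either one-way ANOVA or Kruskal–Wallis, followed
(on rejection) by Dunn's rank-based pairwise test. Holm's correction is
used ("appropriate correction" being otherwise unspecified); Dunn's test is
implemented in-package with tie correction since no installed package
provides it. Effect sizes for the set-size comparison come from the
Friedman test (implemented directly with tie correction and cross-checked
against `stats::friedman.test`): Kendall's W = χ²/(n(k−1)), Cohen's
f = √(W/(1−W)) (so W = 0.3 gives f ≈ 0.65), and post hoc power from a
noncentral-F approximation with df (k−1, (n−1)(k−1)) and noncentrality
f²nk — the power method is labelled approximate in the output because the
original computation is unstated.

## Biomarker selection

Per muscle, the pipeline is fixed: **clean → LASSO → backward stepwise →
group deltas → cluster model**, each stage's features nesting in the
previous stage's.

* **Cleaning** drops any-missing and zero-variance columns, then repeatedly
  finds the most correlated remaining pair (|r| > 0.9) and removes the
  member with the larger mean absolute correlation to everything else, then
  z-scores.
* **LASSO**: penalized logistic regression with lambda chosen by 10-fold
  cross-validated deviance minimization on a seeded fold split. The
  minimizer (not the 1-SE rule) is used: it retains more features, matching
  the scale of the published selections (~25–34 per muscle).
* **Backward stepwise**: AIC-driven elimination from the full logistic
  model, then iterative removal of coefficients with Wald p ≥ 0.05.
  Duplicate (aliased) columns drop later-indexed first. Complete separation
  — common at n = 30 with strong radiomic contrasts — is flagged and a
  ridge-penalized fallback supplies the surviving set without Wald
  p-values.
* **Group deltas**: features are z-scored on the full cohort and group
  means differenced (sarcopenic − non-sarcopenic). Literal within-group
  standardization would force both group means to zero and make every delta
  identically zero, so cohort-level standardization is the only reading
  consistent with reporting non-zero deltas. The two-group Kruskal–Wallis
  test (equivalent to Mann–Whitney, retained as specified) supplies p.
* **Cluster model**: per-subject scores are means of standardized features
  in the variability category (GLCM/GLRLM/GLSZM/GLDM/NGTDM) and the
  structural category (first-order, shape, density); logistic regression on
  both scores yields odds ratios per 1 SD with Wald CIs. Scores are
  computed on the finally selected features (falling back to the cleaned
  matrix when selection retains fewer than two features or one category):
  category-wide averages are uninformative because texture families contain
  complementary pairs (entropy-like vs energy-like) whose contributions
  cancel by construction.

With generator defaults the variability score associates positively and the
structural score negatively with sarcopenia in the majority of seeds —
direction, not magnitude, is the claim, since odds-ratio magnitudes at
n = 30 with near-separable features are unstable. The 4I muscle frequently
yields an empty final feature list; that is an accepted outcome (its tiny
partial-volume cross-sections carry little reliable texture), not an error.

## Orchestration and reproducibility

`run_pipeline()` runs the stages in fixed order and aborts with stage,
subject, and muscle context on any error. Every tunable (bin width, filter
thresholds, set geometry, histogram edges, statistical parameters) lands in
the output manifest together with the seed and a config hash; identical
configurations reproduce identical numbers. `feature_mode = "density"`
restricts extraction to pooled mean/SD density — the protocol's headline
error metric — and runs a 30-subject cohort in seconds;
`feature_mode = "full"` adds the 104-feature vectors and the biomarker
stage. A thin command-line wrapper (`exec/respiromics`) exposes `simulate`
and `run`; all other operations are ordinary package functions.

```{r example, eval = FALSE}
cfg <- pipeline_config(cohort = cohort_config(n_subjects = 30, seed = 1L),
                       feature_mode = "density", seed = 1L)
res <- run_pipeline(cfg, out_dir = "run1")
density_mae(res)    # MAE (HU) per muscle and set size
```

## Known limitations

* The generator's heterogeneity mechanisms (fat ramp, axial gradient, belly
  broadening) are stylized surrogates for phenomena the source cohort only
  reports qualitatively; their parameters are design choices, not fitted
  values.
* Surface area (hence sphericity) uses the corrected voxel-face estimator,
  exact only asymptotically for smooth convex shapes; maximum 3D diameter
  switches to a support-point approximation above 4000 boundary candidates.
* The feature count (104) is the package's own; the source analysis
  reports 118 features from unreported extraction settings, and no attempt
  is made to match that count.
* Wald CIs and stepwise p-values are unreliable under separation; such
  results are flagged rather than suppressed.
* The power computation for the Friedman effect size is an approximation;
  the output says so.
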
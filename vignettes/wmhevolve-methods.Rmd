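---
title: "Methods: lesion-location analysis of WMH burden and evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-location analysis of WMH burden and evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wmhevolve implements a complete analysis chain for one question in cerebral
small vessel disease research: how the extent and anatomical location of
recent small subcortical infarcts (RSSI) and lacunes relate to white matter
hyperintensity (WMH) volume, spatial distribution, and one-year evolution.
This vignette explains the models and procedures, the tunable parameters and
their defaults, what the synthetic cohort generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## The analysis chain

Inputs are binary lesion masks on one common 3D grid — per subject: baseline
WMH, one-year WMH where available, the RSSI, and old stroke lesions — plus a
per-subject clinical table (age, sex, diabetes, hypertension, hyperlipidemia,
four-level smoking status, RSSI and lacune location codes on a fixed
7-region-by-hemisphere proforma, lacune count, intracranial volume). The
package deliberately does no registration: masks must already be
grid-congruent, and anything else is an error, not a resample.

Five stages build on those inputs:

1. **Segmentation** (optional, when intensity volumes exist): each channel is
   robustly rescaled to its 1st–99th percentile window, the fused scalar is
   the voxel-wise minimum of the two channels (a WMH voxel must be bright on
   both sequences), and two thresholds split the suprathreshold volume into
   *intense* and *less-intense* tiers that always partition the total. This
   is a simplified conjunction rule for red–green colour-fusion segmentation,
   not a port of any specific tool. Stroke lesions are delineated by seeded
   region growing: the 26-connected component of the suprathreshold set
   containing the seed.
2. **Volumetrics**: volumes in ml are voxel counts times voxel volume;
   normalised volumes are `100 * ml / ICV` (%ICV). WMH evolution between
   timepoints is a ternary coded map — regressed (baseline only), stable
   (both), progressed (follow-up only) — whose codes conserve volume exactly:
   stable + progressed reassembles the follow-up mask and stable + regressed
   the baseline mask.
3. **Subject-level statistics**: ordinary least squares for
   WMH-volume-on-lesion-measure regressions and ANCOVA-style models of
   one-year change (a linear model with categorical location terms and
   continuous covariates, all models accounting for age); the Kruskal–Wallis
   test with tie correction for per-location volume comparisons; a
   rank-based Levene test for homogeneity of variance. Every location model
   can run twice: once coding each subject by the primary (largest) RSSI
   cluster, once with a composite code keeping all clusters of multi-cluster
   subjects.
4. **Voxel-wise lesion mapping**: per contrast (subjects with the
   lesion in a target location — optionally restricted to carriers of one
   risk factor — versus subjects with the lesion elsewhere and, when
   conditioned, without that factor), the binary WMH indicator is compared at
   every voxel with the tie-corrected Kruskal–Wallis statistic, which on 0/1
   data reduces to a two-sample rank test and has a closed form in the
   per-group lesion counts. Benjamini–Hochberg FDR correction is applied over
   the tested family at 0.05 and 0.01, and suprathreshold counts are reported
   with their ml equivalents.
5. **Voxel association model**: a ridge-penalised support-vector-style linear
   regression, fitted by stochastic gradient descent, of an encoded RSSI
   location on the high-dimensional sparse voxel matrix of WMH fate
   (+1 progressed / −1 regressed / 0 otherwise), with age alongside as an
   unpenalised covariate. The signed weight map splits into positive and
   negative association maps, displayed after rescaling each to half its own
   maximum.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_overlap` | 2 subjects | lesion-overlap floor: voxels lesioned in fewer subjects are excluded from testing *and* from the FDR family, so untestable voxels never inflate the family size |
| FDR `alphas` | 0.05, 0.01 | the two reported significance cut-offs |
| voxel size | from mask headers; 1 mm isotropic in the worked examples | sets the count-to-ml conversion (14,253 voxels = 14.25 ml at 1 mm) |
| `lambda` | 1/47 | ridge strength of the association model, kept as the reference analysis' opaque constant; `lambda_times_n` switches to the per-sum-loss normalisation convention, since reference implementations differ |
| `epsilon` | IQR(response)/13.49 | insensitivity half-width of the SVR loss, the dispersion-based convention of common SVR implementations |
| `epochs`, `eta0`, `decay` | 50, 0.05, `eta0*lambda` | SGD schedule `eta0/(1 + decay*t)` with per-epoch shuffling fixed by a seed and Polyak–Ruppert averaging over the second half of training |
| segmentation `low_thr`, `high_thr` | free | the intense/less-intense split has no published numeric thresholds; they are explicit parameters |

The FDR family is per contrast (one map, one family), not pooled across
contrasts, matching how per-contrast results tables report each row
independently.

## The synthetic cohort generator

No clinical dataset ships with the package, so `generate_cohort()` produces
complete study inputs whose marginal structure matches the cohort the
analyses were designed for: n = 118 by default, age 64.93 (SD 11.75) years,
ICV 1469.20 (SD 139.82) ml, diabetes 10.2%, hypertension 69.5%,
hyperlipidemia 61.9%, smoking status drawn from the observed four-level
counts renormalised to sum to one, RSSI present in 79/118 with per-region,
per-hemisphere frequencies proportional to the observed counts, lacunes
likewise, and follow-up available for 88/118.

Spatial WMH arise from a fixed periventricular-like probability template (a
Gaussian in the distance from the grid's central axis) scaled by a lognormal
per-subject severity that increases with age, thresholded by per-voxel
Bernoulli draws and morphologically closed (6-neighbour structuring element)
so lesions are spatially clustered rather than salt-and-pepper — the
downstream statistics assume spatially coherent lesions. The default grid is
32^3 at 2 mm isotropic: a deliberately scaled-down standard space in which
template WMH land in the cohort's 5–50 ml range while simulations stay cheap
enough to replicate hundreds of times.

Two planted effects are the generator's contract with the validation suite:

- **Lacune link**: lacune counts are Poisson with rate
  `0.5 + 0.37 * WMH %ICV` — counts are small non-negative integers, and the
  slope mirrors the reported association of lacune number with baseline WMH
  burden.
- **Change link**: one-year progression voxels are sampled from successive
  26-neighbour dilation rings of the baseline mask (confluent growth) with
  expected volume `1.0 + 2.9 * RSSI ml`, and regression voxels from the
  mask-interior boundary with expected volume 0.5 ml, so the expected change
  is linear in RSSI volume with slope 2.9 ml/ml, mirroring the reported
  change association, atop a small net positive drift.

A `planted_region` (with `planted_p_target` = 0.60 versus
`planted_p_other` = 0.15 per voxel) gives one designated location-by-risk
group excess WMH probability in a known set of voxels; it is injected after
the morphological closing and *replaces* the template there, so the planted
per-voxel probabilities are exact and recovery statistics are clean.
`generate_structural_pair()` renders any subject's tier masks as
three-level FLAIR-like/T2-like volumes with optional Gaussian noise, to
exercise the segmentation stage against a known truth.

What the generator does **not** emulate: MRI physics and partial-volume
effects, anatomically realistic lesion shapes or nonlinear anatomical
variability, spatial correlation between the RSSI site and the WMH field
beyond the planted effects, and cavitation or visually scored infarct
progression. Passing tests therefore demonstrate that the statistical
machinery is correct and well calibrated under the declared generative
model — not that it would detect any particular effect in real scanner data.

## Numerical and design choices

- **Kruskal–Wallis in deviation form.** Both the subject-level test and the
  closed-form voxel-wise version compute the statistic from group mean-rank
  deviations, `H = 12/(N(N+1)) * sum(n_j (rbar_j - (N+1)/2)^2) / C`, with the
  tie factor `C = 1 - sum(t^3 - t)/(N^3 - N)`. The textbook rank-sum form
  cancels two large terms and loses about eight digits at voxels where H is
  near zero; the deviation form is exact to rounding, which is what lets the
  suite assert agreement with an independent rank implementation at 1e-10.
  When every observation is tied, H is defined as 0 with P = 1 (returned,
  not an error). For total n of 12 or fewer the p-value comes from the
  permutation distribution (exact enumeration for two groups) rather than
  the chi-squared approximation.
- **Quantile convention.** All interquartile ranges use linear interpolation
  between order statistics (R type 7), declared once and used everywhere;
  per-location summary tables report medians and IQRs in both ml and %ICV.
- **Binarisation tolerance.** Masks binarise on load at `|v| > 0.5`, so
  interpolated float masks survive a resampling round trip.
- **Region-growing connectivity** is 26-neighbour, stated explicitly because
  common practice varies and the choice changes component membership.
- **Missing data** are handled by listwise deletion with the dropped-row
  count reported on every fit; change analyses use only followed-up
  subjects, with no imputation.
- **Model orientation of the association fit.** The fitted model takes the
  encoded location as response and the voxel fate matrix as predictors,
  because the ridge/SGD machinery is motivated precisely by high-dimensional
  sparse *predictors*; the location coding (proforma integer of the primary
  cluster, or a region indicator) is explicit because no published coding
  exists. Both the orientation and the coding are flagged choices, not
  assertions about the reference analysis; an indicator response is the
  recommended variant when a single region is of interest.
- **SGD validation.** With squared loss, epsilon 0, no intercept and no
  covariates, the SGD solution must match the closed-form ridge estimator
  `(X'X + n*lambda*I)^{-1} X'y`; the suite asserts 1e-3 relative agreement at
  n = 40, p = 15 over ten seeds, using 3000 epochs for the check (training
  at that size costs about a second). The epsilon-insensitive default is
  used for real maps.
- **Per-stage seeds.** The pipeline derives each stage's seed as a fixed
  hash of the global seed and the stage name (kept below 2^31), so stages
  rerun in isolation reproduce their slice of a full run, and manifests of
  two runs with one config are checksum-identical.

## Calibration of the planted-effect recovery

The recovery harness regenerates cohorts of n = 500 on a 24^3 grid over 20
seeds and asks whether each planted slope lies inside its estimated 95%
confidence interval in at least 90% of seeds. Both planted links produce
*heteroscedastic* noise by construction — Poisson counts and voxel-sampling
noise have variance proportional to their mean — so classical OLS standard
errors are anticonservative there (89–93% empirical coverage in a 100-seed
audit). The recovery intervals therefore use
heteroscedasticity-consistent (HC3 sandwich) standard errors, available via
`tidy(fit, conf.int = TRUE, robust = TRUE)`; point estimates and the
reported t-based p-values are unchanged. This is an interval-calibration
choice, not a loosening: HC3 intervals are asymptotically correct under
exactly the variance structure the generator creates, and the same audit
puts their coverage at approximately 95%.

Problem sizes used by the validation suite, chosen to keep hundreds of
replicates cheap: null FDR calibration uses 200 cohorts of n = 60 on a 32^3
grid; planted-region recovery one cohort of n = 120 with a 2,000-voxel
planted block; slope recovery 20 cohorts of n = 500 on 24^3; the ridge
oracle n = 40, p = 15; conservation 100 random 16^3 mask pairs.

## Known limitations

- The fusion segmentation is a minimal stand-in for multispectral WMH
  segmentation; it has no bias-field handling, no skull stripping, and its
  thresholds are data-set specific.
- The voxel-wise test is two-group (location versus elsewhere) by default;
  a k-group comparison across all locations simultaneously is possible with
  `kruskal_groups()` on extracted voxel columns but is not the battery
  default, because group-versus-rest is what the per-location results
  tables describe.
- SGD weights carry no inferential error bars; the association maps are
  exploratory, and the package deliberately offers no p-values for them.
- With very small groups (a handful of subjects in a location), the
  location summaries are flagged `descriptive_only` rather than suppressed;
  treat them accordingly.
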
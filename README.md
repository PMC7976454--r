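# wmhevolve

Analysis tools for a central question in cerebral small vessel disease (SVD)
research: how the **extent and anatomical location of recent small
subcortical infarcts (RSSI) and lacunes** relate to **white matter
hyperintensity (WMH) volume, spatial distribution, and one-year evolution**.
It is written for imaging researchers who have co-registered binary lesion
masks (baseline WMH, follow-up WMH, RSSI, old stroke lesions) and a clinical
cohort table, and who want the complete, reproducible statistical chain from
masks to results tables and association maps.

## What it computes

- **Volumetrics** — lesion volumes in ml and as %ICV
  (`100 * ml / intracranial volume`); ternary WMH **evolution maps** coding
  each voxel as regressed / stable / progressed between timepoints, with
  exact volume conservation (stable + progressed = follow-up,
  stable + regressed = baseline); median (Q1, Q3) summary tables per lesion
  location.
- **Subject-level models** — linear regression of WMH burden on lesion
  measures and ANCOVA-style models of one-year WMH change
  (`fit_wmh_lm()` / `fit_wmh_ancova()`, broom-style `tidy()`/`glance()`
  output with B, SE, P per term), Kruskal–Wallis tests with tie correction
  (`kruskal_groups()`), and a rank-based Levene test (`levene_ranked()`).
  Location models run on either the primary RSSI cluster or a multi-cluster
  composite code (`recode_locations()`).
- **Voxel-wise lesion mapping** — masks stack into a 4D array
  (`build_mask4d()`); at every voxel lesioned in at least `min_overlap`
  subjects, the tie-corrected Kruskal–Wallis statistic

  `H = 12/(N(N+1)) * sum_j n_j (rbar_j - (N+1)/2)^2 / C`,
  `C = 1 - sum(t^3 - t)/(N^3 - N)`,

  compares the binary WMH indicator between subjects with the lesion in a
  target location (optionally restricted to a risk-factor subgroup) and
  subjects with it elsewhere; Benjamini–Hochberg FDR correction at 0.05 and
  0.01 over the tested family; suprathreshold voxel counts with ml
  equivalents (`run_contrast_battery()`).
- **Voxel association model** — ridge-penalised support-vector-style
  regression (default penalty 1/47), fitted by stochastic gradient descent
  with averaging, of encoded RSSI location on the sparse subject-by-voxel
  matrix of WMH fate (+1 progressed / −1 regressed), age unpenalised
  alongside; signed weight maps split into positive/negative association
  fields and rescaled to 50% of each maximum for display
  (`fit_sgd_ridge()`, `rescale_for_display()`).
- **Segmentation** (optional) — two-channel red–green fusion
  (`rg_fuse()`: robust percentile rescaling, fused scalar = voxel-wise
  minimum), two-threshold split into intense / less-intense WMH tiers
  (`segment_wmh()`), and 26-connected seeded region growing for stroke
  lesions (`region_grow()`).
- **Synthetic cohorts** — `generate_cohort()` produces complete study inputs
  (masks + cohort table) matching the demographic and lesion-frequency
  marginals of a 118-patient lacunar-stroke cohort, with planted
  lacune-count and WMH-change effects and an optional planted excess-WMH
  region for end-to-end validation.

## Worked example

```r
library(wmhevolve)

cfg <- generator_config(n_subjects = 60, seed = 42)
co  <- generate_cohort(cfg)
co
#> <wmh_cohort> 60 subjects (43 followed up) on 32x32x32 grid, seed 42

# lacune count vs WMH burden (%ICV), accounting for age
fit <- fit_wmh_lm(co$cohort, wmh_pct_icv ~ lacune_count + age)
tidy(fit)
#> # A tibble: 3 x 5
#>   term         estimate std.error statistic p.value
#>   <chr>           <dbl>     <dbl>     <dbl>   <dbl>
#> 1 (Intercept)   -0.273     1.68      -0.162 0.871
#> 2 lacune_count   0.606     0.191      3.16  0.00249
#> 3 age            0.0510    0.0256     2.00  0.0508

# voxel-wise comparison: RSSI in centrum semiovale vs elsewhere
st  <- build_mask4d(co$masks$wmh_baseline, names(co$masks$wmh_baseline))
cs  <- wmh_contrast(co$cohort, "rssi", "centrum semiovale")
bat <- run_contrast_battery(st, co$cohort, list(cs))
bat$results
#> # A tibble: 1 x 8
#>   contrast          n_target n_comparison m_tested n_sig_05 ml_05 n_sig_01 ml_01
#> 1 rssi in centrum …       20           19    21182        0     0        0     0

# one subject's WMH fate over the year
id  <- names(co$masks$wmh_followup)[1]
evo <- evolution_mask(co$masks$wmh_baseline[[id]], co$masks$wmh_followup[[id]])
evolution_volumes(evo)
#> # A tibble: 4 x 4
#>    code fate       n_voxels volume_ml
#> 1     0 never         16144   129.
#> 2     1 regressed        63     0.504
#> 3     2 stable        15670   125.
#> 4     3 progressed      891     7.13
```

Reading of the numbers: each additional lacune is associated with ~0.61
percentage points more WMH %ICV in this synthetic cohort (P = 0.0025); the
voxel battery finds no suprathreshold voxels because this cohort has no
planted spatial effect (WMH location is independent of RSSI location under
the null generator), which is exactly the FDR behaviour the validation suite
quantifies; and the example subject progressed by 7.13 ml while regressing
0.50 ml, a net one-year WMH increase of 6.6 ml.

The full chain (simulate → volumetrics → models → voxel maps → association →
report tables, with a checksummed run manifest) is one call:

```r
run <- run_pipeline(pipeline_config("out/", seed = 7,
                                    generator = list(n_subjects = 118)))
```

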
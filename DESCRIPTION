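Package: wmhevolve
Title: White Matter Hyperintensity Distribution and One-Year Evolution
    After Lacunar Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the extent and anatomical location of
    recent small subcortical infarcts (RSSI) and lacunes relate to white
    matter hyperintensity (WMH) volume, spatial distribution and one-year
    evolution in cerebral small vessel disease. Provides binary lesion-mask
    input/output and 4D stacking on a common grid, a simplified two-channel
    fusion WMH segmentation with an intense/less-intense tier split and
    seeded region growing, volumetrics (millilitre and percent-intracranial-
    volume accounting, ternary WMH evolution maps), subject-level regression,
    ANCOVA, Kruskal-Wallis and rank-based Levene tests, mass-univariate
    voxel-wise Kruskal-Wallis lesion mapping with Benjamini-Hochberg false
    discovery rate control, a ridge-penalised support-vector-style voxel
    association model fitted by stochastic gradient descent, and a synthetic
    cohort generator with planted effects for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    RNifti,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
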
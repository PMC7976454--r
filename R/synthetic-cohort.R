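#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of a hospital lacunar-stroke cohort
#' of 118 patients (88 with one-year follow-up): age 64.93 (SD 11.75) years,
#' intracranial volume 1469.20 (SD 139.82) ml, risk-factor prevalences
#' (diabetes 10.2%, hypertension 69.5%, hyperlipidemia 61.9%, four-level
#' smoking status), RSSI present in 79/118 subjects with anatomical location
#' frequencies proportional to the observed per-region, per-hemisphere counts,
#' and lacunes whose expected count rises linearly with WMH burden.
#'
#' Planted effects are the generator's contract with the validation suite:
#' `effect_lacune_slope` is the expected number of lacunes per unit baseline
#' WMH %ICV, and `effect_change_slope` the expected one-year WMH volume change
#' (ml) per ml of RSSI volume. `planted_region` (a 3-column matrix of voxel
#' indices) designates voxels where subjects in `planted_group` have WMH with
#' probability `planted_p_target` per voxel while everyone else has
#' `planted_p_other`, overriding the spatial template there.
#'
#' @param n_subjects number of subjects.
#' @param grid_dims,voxel_dims_mm common-space grid (3 positive integers) and
#'   voxel size in mm. The default 32^3 grid of 2 mm voxels is a scaled-down
#'   standard space that keeps WMH volumes in the cohort's 5-50 ml range.
#' @param age_mean_sd,icv_mean_sd mean and SD of age (years) and ICV (ml).
#' @param male_fraction probability of male sex.
#' @param prevalence named probabilities for `diabetes`, `hypertension`,
#'   `hyperlipidemia`.
#' @param smoking_probs named probabilities for levels
#'   `current`, `recent`, `ex`, `never`; must sum to 1.
#' @param rssi_fraction probability a subject carries an RSSI.
#' @param location_weights,lacune_location_weights named non-negative weights
#'   over `"region,hemisphere"` codes for RSSI clusters and lacunes.
#' @param multi_cluster_rate probability an RSSI-positive subject carries a
#'   second cluster (0 by default; the study cohort had 6/118 such patients).
#' @param followup_rate probability of having one-year data.
#' @param effect_lacune_slope expected lacunes per unit WMH %ICV.
#' @param lacune_base_rate baseline Poisson rate of the lacune count.
#' @param effect_change_slope expected WMH change (ml) per ml RSSI volume.
#' @param progression_drift_ml,regression_ml expected progression unrelated to
#'   RSSI volume and expected regressed volume (ml).
#' @param rssi_volume_meanlog,rssi_volume_sdlog lognormal parameters of RSSI
#'   cluster volume (ml).
#' @param old_lesion_fraction,old_volume_meanlog,old_volume_sdlog prevalence
#'   and lognormal volume parameters of old stroke lesions.
#' @param wmh_template_peak peak per-voxel WMH probability of the spatial
#'   template at unit severity.
#' @param wmh_template_sigma Gaussian radius (voxels) of the periventricular
#'   template; default `min(grid_dims)/5`.
#' @param severity_sdlog lognormal spread of the per-subject severity scalar.
#' @param severity_age_coef increase of log-severity per SD of age.
#' @param planted_region integer matrix (n x 3) of voxel coordinates, or NULL.
#' @param planted_group list with elements `feature` (`"rssi"`), `region`,
#'   optional `hemisphere`, optional `risk` (one of the risk-flag column
#'   names); subjects matching it form the designated group.
#' @param planted_p_target,planted_p_other per-voxel WMH probabilities inside
#'   `planted_region` for the designated group and for everyone else.
#' @param morph_close logical; morphologically close baseline masks so lesions
#'   are spatially clustered rather than salt-and-pepper.
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_subjects = 118L,
    grid_dims = c(32L, 32L, 32L),
    voxel_dims_mm = c(2, 2, 2),
    age_mean_sd = c(64.93, 11.75),
    icv_mean_sd = c(1469.20, 139.82),
    male_fraction = 67 / 118,
    prevalence = c(diabetes = 0.102, hypertension = 0.695, hyperlipidemia = 0.619),
    smoking_probs = c(current = 46, recent = 5, ex = 31, never = 35) / 117,
    rssi_fraction = 79 / 118,
    location_weights = default_rssi_location_weights(),
    lacune_location_weights = default_lacune_location_weights(),
    multi_cluster_rate = 0,
    followup_rate = 88 / 118,
    effect_lacune_slope = 0.37,
    lacune_base_rate = 0.5,
    effect_change_slope = 2.9,
    progression_drift_ml = 1.0,
    regression_ml = 0.5,
    rssi_volume_meanlog = log(1.0),
    rssi_volume_sdlog = 0.5,
    old_lesion_fraction = 42 / 118,
    old_volume_meanlog = log(1.5),
    old_volume_sdlog = 0.6,
    wmh_template_peak = 0.5,
    wmh_template_sigma = NULL,
    severity_sdlog = 0.6,
    severity_age_coef = 0.25,
    planted_region = NULL,
    planted_group = NULL,
    planted_p_target = 0.60,
    planted_p_other = 0.15,
    morph_close = TRUE,
    seed = 1L) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 0) {
    abort("`n_subjects` must be a single non-negative integer.")
  }
  if (length(grid_dims) != 3L || any(grid_dims <= 0) || any(grid_dims != round(grid_dims))) {
    abort("`grid_dims` must be 3 positive integers.")
  }
  check_voxel_dims(voxel_dims_mm)
  probs <- c(prevalence, male_fraction = male_fraction,
             rssi_fraction = rssi_fraction, followup_rate = followup_rate,
             old_lesion_fraction = old_lesion_fraction,
             multi_cluster_rate = multi_cluster_rate,
             planted_p_target = planted_p_target,
             planted_p_other = planted_p_other)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1].")
  need <- c("diabetes", "hypertension", "hyperlipidemia")
  if (!all(need %in% names(prevalence))) {
    abort("`prevalence` must name diabetes, hypertension and hyperlipidemia.")
  }
  lv <- c("current", "recent", "ex", "never")
  if (!setequal(names(smoking_probs), lv)) abort("`smoking_probs` must name the four smoking levels.")
  smoking_probs <- smoking_probs[lv]
  if (abs(sum(smoking_probs) - 1) > 1e-9) abort("smoking level probabilities must sum to 1.")
  for (w in list(location_weights, lacune_location_weights)) {
    if (any(w < 0) || sum(w) <= 0) abort("location weights must be non-negative and normalizable.")
    bad <- setdiff(names(w), all_location_codes())
    if (length(bad)) abort(sprintf("unknown location code(s) in weights: %s", paste(bad, collapse = "; ")))
  }
  if (!is.null(planted_region)) {
    planted_region <- as.matrix(planted_region)
    if (ncol(planted_region) != 3L) abort("`planted_region` must be an n x 3 coordinate matrix.")
    if (any(planted_region < 1) || any(t(planted_region) > grid_dims)) {
      abort("`planted_region` coordinates fall outside the grid.")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), grid_dims = as.integer(grid_dims),
      voxel_dims_mm = as.numeric(voxel_dims_mm),
      age_mean_sd = age_mean_sd, icv_mean_sd = icv_mean_sd,
      male_fraction = male_fraction, prevalence = prevalence,
      smoking_probs = smoking_probs, rssi_fraction = rssi_fraction,
      location_weights = location_weights / sum(location_weights),
      lacune_location_weights = lacune_location_weights / sum(lacune_location_weights),
      multi_cluster_rate = multi_cluster_rate, followup_rate = followup_rate,
      effect_lacune_slope = effect_lacune_slope, lacune_base_rate = lacune_base_rate,
      effect_change_slope = effect_change_slope,
      progression_drift_ml = progression_drift_ml, regression_ml = regression_ml,
      rssi_volume_meanlog = rssi_volume_meanlog, rssi_volume_sdlog = rssi_volume_sdlog,
      old_lesion_fraction = old_lesion_fraction,
      old_volume_meanlog = old_volume_meanlog, old_volume_sdlog = old_volume_sdlog,
      wmh_template_peak = wmh_template_peak,
      wmh_template_sigma = wmh_template_sigma %||% (min(grid_dims) / 5),
      severity_sdlog = severity_sdlog, severity_age_coef = severity_age_coef,
      planted_region = planted_region, planted_group = planted_group,
      planted_p_target = planted_p_target, planted_p_other = planted_p_other,
      morph_close = isTRUE(morph_close), seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @details `default_rssi_location_weights()` and
#'   `default_lacune_location_weights()` are proportional to the cohort's
#'   per-region, per-hemisphere RSSI and lacune counts.
#' @export
default_rssi_location_weights <- function() {
  w <- c(9, 13, 0, 0, 16, 18, 6, 7, 3, 7, 0, 0, 2, 0)
  setNames(w, all_location_codes())
}

#' @rdname generator_config
#' @export
default_lacune_location_weights <- function() {
  w <- c(15, 17, 1, 1, 14, 18, 4, 3, 2, 3, 2, 1, 5, 2)
  setNames(w, all_location_codes())
}

#' Spatial WMH probability template
#'
#' Smooth periventricular-like field: probability decays as a Gaussian in the
#' distance from the grid's central vertical axis, peaking at `peak`.
#'
#' @param grid_dims 3 positive integers.
#' @param peak peak probability.
#' @param sigma Gaussian radius in voxels.
#' @return 3D array of per-voxel probabilities.
#' @export
wmh_template <- function(grid_dims, peak = 0.5, sigma = min(grid_dims) / 5) {
  cx <- (grid_dims[1] + 1) / 2
  cy <- (grid_dims[2] + 1) / 2
  dx <- (seq_len(grid_dims[1]) - cx)
  dy <- (seq_len(grid_dims[2]) - cy)
  d2 <- outer(dx^2, dy^2, "+")
  plane <- peak * exp(-d2 / (2 * sigma^2))
  array(rep(plane, grid_dims[3]), grid_dims)
}

region_centres <- function(grid_dims) {
  # plausible, fixed fractional positions; left hemisphere x < 0.5 < right
  frac <- rbind(
    c(0.35, 0.45, 0.40), c(0.65, 0.45, 0.40),  # capsule/lentiform
    c(0.30, 0.55, 0.55), c(0.70, 0.55, 0.55),  # internal border zone
    c(0.32, 0.50, 0.70), c(0.68, 0.50, 0.70),  # centrum semiovale
    c(0.42, 0.55, 0.38), c(0.58, 0.55, 0.38),  # thalamus
    c(0.45, 0.62, 0.20), c(0.55, 0.62, 0.20),  # brainstem
    c(0.35, 0.75, 0.15), c(0.65, 0.75, 0.15),  # cerebellum
    c(0.30, 0.72, 0.45), c(0.70, 0.72, 0.45)   # optical radiation
  )
  centres <- sweep(frac, 2, grid_dims, "*")
  rownames(centres) <- all_location_codes()
  centres
}

sphere_mask <- function(grid_dims, voxel_dims_mm, centre, volume_ml) {
  r_mm <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  r_vox <- r_mm / voxel_dims_mm
  dx2 <- ((seq_len(grid_dims[1]) - centre[1]) / r_vox[1])^2
  dy2 <- ((seq_len(grid_dims[2]) - centre[2]) / r_vox[2])^2
  dz2 <- ((seq_len(grid_dims[3]) - centre[3]) / r_vox[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  d2 <= 1
}

in_planted_group <- function(config, rssi_primary_region, rssi_primary_hemi, risk_flags) {
  pg <- config$planted_group
  if (is.null(pg)) return(FALSE)
  ok <- identical(rssi_primary_region, pg$region)
  if (!is.null(pg$hemisphere)) ok <- ok && identical(rssi_primary_hemi, pg$hemisphere)
  if (!is.null(pg$risk)) ok <- ok && isTRUE(risk_flags[[pg$risk]])
  ok
}

#' Generate a complete synthetic study cohort
#'
#' Produces, deterministically for a fixed seed, the full set of inputs the
#' downstream analyses expect: a per-subject cohort table and, per subject,
#' a baseline WMH mask (with an intense-tier core), a one-year follow-up WMH
#' mask for followed-up subjects, an RSSI mask and an old-stroke-lesion mask,
#' all on one common grid.
#'
#' Baseline WMH arise from a per-subject severity scalar multiplying the
#' spatial template, per-voxel Bernoulli draws, and (optionally) a
#' morphological closing so lesions are clustered. Lacune counts are Poisson
#' with rate `lacune_base_rate + effect_lacune_slope * WMH %ICV`. Follow-up
#' masks add progression voxels sampled from successive 26-neighbour dilation
#' rings of the baseline mask with expected volume
#' `progression_drift_ml + effect_change_slope * rssi_volume_ml`, and remove
#' regression voxels sampled from the mask-interior boundary with expected
#' volume `regression_ml`. Voxels of `planted_region` are governed by the
#' planted probabilities instead of the template (injected after closing so
#' the planted per-voxel probabilities are exact).
#'
#' @param config a [generator_config()].
#' @return A `wmh_cohort` list: `cohort` (tibble), `masks` (lists
#'   `wmh_baseline`, `wmh_intense`, `wmh_followup`, `rssi`, `old_lesion`,
#'   each named by subject id), `template`, and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  gd <- config$grid_dims
  vv <- voxel_volume_ml(config$voxel_dims_mm)
  template <- wmh_template(gd, config$wmh_template_peak, config$wmh_template_sigma)
  centres <- region_centres(gd)
  planted_idx <- if (!is.null(config$planted_region)) {
    config$planted_region[, 1] +
      (config$planted_region[, 2] - 1L) * gd[1] +
      (config$planted_region[, 3] - 1L) * gd[1] * gd[2]
  } else integer(0)

  masks <- list(wmh_baseline = list(), wmh_intense = list(),
                wmh_followup = list(), rssi = list(), old_lesion = list())
  rows <- vector("list", n)
  if (n == 0L) {
    return(structure(list(cohort = empty_cohort(), masks = masks,
                          template = template, config = config),
                     class = "wmh_cohort"))
  }

  for (i in seq_len(n)) {
    id <- sprintf("S%04d", i)
    age <- rnorm(1, config$age_mean_sd[1], config$age_mean_sd[2])
    sex <- if (runif(1) < config$male_fraction) "male" else "female"
    icv <- max(800, rnorm(1, config$icv_mean_sd[1], config$icv_mean_sd[2]))
    flags <- lapply(config$prevalence, function(p) runif(1) < p)
    smoking <- sample(names(config$smoking_probs), 1, prob = config$smoking_probs)
    has_fu <- runif(1) < config$followup_rate

    # RSSI clusters (largest first), mask-derived volumes
    rssi_codes <- character(0)
    rssi_mask <- array(FALSE, gd)
    if (runif(1) < config$rssi_fraction) {
      n_clust <- 1L + rbinom(1, 1, config$multi_cluster_rate)
      codes <- sample(names(config$location_weights), n_clust,
                      replace = TRUE, prob = config$location_weights)
      vols <- rlnorm(n_clust, config$rssi_volume_meanlog, config$rssi_volume_sdlog)
      cl_masks <- lapply(seq_len(n_clust), function(k) {
        sphere_mask(gd, config$voxel_dims_mm, centres[codes[k], ], vols[k])
      })
      cl_vox <- vapply(cl_masks, sum, numeric(1))
      ord <- order(cl_vox, decreasing = TRUE)
      rssi_codes <- codes[ord]
      for (m in cl_masks) rssi_mask <- rssi_mask | m
    }
    rssi_ml <- sum(rssi_mask) * vv
    rssi_primary <- if (length(rssi_codes)) {
      sub(",[^,]*$", "", rssi_codes[[1]])
    } else "none"
    rssi_primary_hemi <- if (length(rssi_codes)) sub("^.*,", "", rssi_codes[[1]]) else NA_character_

    # old stroke lesion
    old_mask <- array(FALSE, gd)
    if (runif(1) < config$old_lesion_fraction) {
      code <- sample(names(config$lacune_location_weights), 1,
                     prob = config$lacune_location_weights)
      old_mask <- sphere_mask(gd, config$voxel_dims_mm, centres[code, ],
                              rlnorm(1, config$old_volume_meanlog, config$old_volume_sdlog))
    }
    old_ml <- sum(old_mask) * vv

    # baseline WMH: severity x template, Bernoulli, closing
    z_age <- (age - config$age_mean_sd[1]) / config$age_mean_sd[2]
    severity <- exp(config$severity_age_coef * z_age +
                      rnorm(1, 0, config$severity_sdlog))
    p_field <- pmin(0.95, severity * template)
    base <- array(runif(prod(gd)) < p_field, gd)
    if (config$morph_close) base <- close_cross(base)
    if (length(planted_idx)) {
      in_group <- in_planted_group(config, rssi_primary, rssi_primary_hemi, flags)
      p_plant <- if (in_group) config$planted_p_target else config$planted_p_other
      base[planted_idx] <- runif(length(planted_idx)) < p_plant
    }
    wmh_ml <- sum(base) * vv
    intense <- erode_cross(base)
    intense_ml <- sum(intense) * vv
    wmh_pct <- 100 * wmh_ml / icv

    # lacunes: Poisson, rate linear-positive in WMH %ICV
    lac_rate <- config$lacune_base_rate + config$effect_lacune_slope * wmh_pct
    lac_count <- rpois(1, max(0, lac_rate))
    lac_codes <- if (lac_count > 0) {
      sample(names(config$lacune_location_weights), lac_count,
             replace = TRUE, prob = config$lacune_location_weights)
    } else character(0)

    # follow-up: confluent progression ring growth, interior regression
    fu <- NULL
    fu_ml <- fu_intense_ml <- NA_real_
    if (has_fu) {
      target_ml <- config$progression_drift_ml + config$effect_change_slope * rssi_ml
      n_prog <- rpois(1, max(0, target_ml) / vv)
      pool_src <- if (any(base)) base else {
        seed_arr <- array(FALSE, gd)
        seed_arr[ceiling(gd[1] / 2), ceiling(gd[2] / 2), ceiling(gd[3] / 2)] <- TRUE
        seed_arr
      }
      grown <- pool_src
      for (k in 1:12) {
        if (sum(grown) - sum(pool_src) >= n_prog) break
        grown <- dilate_box(grown)
      }
      pool <- which(grown & !base)
      prog_idx <- if (length(pool)) sample(pool, min(n_prog, length(pool))) else integer(0)
      boundary <- which(base & !erode_cross(base))
      n_reg <- rpois(1, config$regression_ml / vv)
      reg_idx <- if (length(boundary)) sample(boundary, min(n_reg, length(boundary))) else integer(0)
      fu <- base
      fu[reg_idx] <- FALSE
      fu[prog_idx] <- TRUE
      fu_ml <- sum(fu) * vv
      fu_intense_ml <- sum(erode_cross(fu)) * vv
    }

    masks$wmh_baseline[[id]] <- lesion_mask(array(as.integer(base), gd), config$voxel_dims_mm)
    masks$wmh_intense[[id]] <- lesion_mask(array(as.integer(intense), gd), config$voxel_dims_mm)
    masks$rssi[[id]] <- lesion_mask(array(as.integer(rssi_mask), gd), config$voxel_dims_mm)
    masks$old_lesion[[id]] <- lesion_mask(array(as.integer(old_mask), gd), config$voxel_dims_mm)
    if (has_fu) {
      masks$wmh_followup[[id]] <- lesion_mask(array(as.integer(fu), gd), config$voxel_dims_mm)
    }

    rows[[i]] <- tibble(
      subject_id = id, age = age, sex = sex,
      diabetes = flags$diabetes, hypertension = flags$hypertension,
      hyperlipidemia = flags$hyperlipidemia, smoking = smoking,
      rssi_locations = paste(rssi_codes, collapse = ";"),
      lacune_count = as.integer(lac_count),
      lacune_locations = paste(lac_codes, collapse = ";"),
      rssi_volume_ml = rssi_ml, old_lesion_volume_ml = old_ml,
      icv_ml = icv, has_followup = has_fu,
      wmh_total_ml = wmh_ml, wmh_intense_ml = intense_ml,
      wmh_less_intense_ml = wmh_ml - intense_ml,
      wmh_total_y1_ml = fu_ml, wmh_intense_y1_ml = fu_intense_ml,
      wmh_less_intense_y1_ml = fu_ml - fu_intense_ml,
      wmh_pct_icv = wmh_pct
    )
  }
  cohort <- validate_cohort(dplyr::bind_rows(rows))
  structure(list(cohort = cohort, masks = masks, template = template,
                 config = config),
            class = "wmh_cohort")
}

empty_cohort <- function() {
  tibble(
    subject_id = character(), age = numeric(), sex = character(),
    diabetes = logical(), hypertension = logical(), hyperlipidemia = logical(),
    smoking = character(), rssi_locations = character(),
    lacune_count = integer(), lacune_locations = character(),
    rssi_volume_ml = numeric(), old_lesion_volume_ml = numeric(),
    icv_ml = numeric(), has_followup = logical(),
    wmh_total_ml = numeric(), wmh_intense_ml = numeric(),
    wmh_less_intense_ml = numeric(), wmh_total_y1_ml = numeric(),
    wmh_intense_y1_ml = numeric(), wmh_less_intense_y1_ml = numeric(),
    wmh_pct_icv = numeric()
  )
}

#' @export
print.wmh_cohort <- function(x, ...) {
  cat(sprintf(
    "<wmh_cohort> %d subjects (%d followed up) on %s grid, seed %d\n",
    nrow(x$cohort), sum(x$cohort$has_followup),
    paste(x$config$grid_dims, collapse = "x"), x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort CSV, all masks as NIfTI (`.nii.gz`) and the generator
#' provenance (config and seed) as YAML.
#'
#' @param x a `wmh_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dataset <- function(x, dir) {
  stopifnot(inherits(x, "wmh_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(x$cohort, file.path(dir, "cohort.csv"))
  for (kind in names(x$masks)) {
    kd <- file.path(dir, kind)
    dir.create(kd, showWarnings = FALSE)
    for (id in names(x$masks[[kind]])) {
      write_mask(x$masks[[kind]][[id]], file.path(kd, paste0(id, ".nii.gz")))
    }
  }
  cfg <- x$config
  cfg$planted_region <- if (is.null(cfg$planted_region)) NULL else
    apply(cfg$planted_region, 1, paste, collapse = ",")
  yaml::write_yaml(unclass(cfg), file.path(dir, "generator.yaml"))
  invisible(dir)
}

#' Simulate a FLAIR-like / T2-like structural pair for one subject
#'
#' Renders the planted WMH tiers as bright voxels over a darker background in
#' two channels, with optional additive Gaussian noise: background, the
#' less-intense tier and the intense tier take three increasing intensity
#' levels per channel, so noiseless thresholding of the fused image recovers
#' the planted tiers exactly.
#'
#' @param wmh_total,wmh_intense [lesion_mask] objects; `wmh_intense` must be a
#'   subset of `wmh_total`.
#' @param noise_sd additive Gaussian noise SD (intensity units, >= 0).
#' @param levels list with numeric length-3 vectors `flair` and `t2` giving
#'   the background / less-intense / intense intensity levels per channel.
#' @param seed RNG seed for the noise.
#' @return List with 3D arrays `flair` and `t2`, plus `voxel_dims_mm`.
#' @export
generate_structural_pair <- function(wmh_total, wmh_intense, noise_sd = 0,
                                     levels = list(flair = c(0.2, 0.55, 0.85),
                                                   t2 = c(0.25, 0.60, 0.90)),
                                     seed = 1L) {
  stopifnot(inherits(wmh_total, "lesion_mask"), inherits(wmh_intense, "lesion_mask"))
  stop_if_incongruent(wmh_total, wmh_intense, "tier masks")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (any(wmh_intense$values > wmh_total$values)) {
    abort("`wmh_intense` must be contained in `wmh_total`.")
  }
  tier <- wmh_total$values + wmh_intense$values  # 0 bg, 1 less-intense, 2 intense
  render <- function(lv) array(lv[tier + 1L], dim(tier))
  set.seed(seed)
  d <- dim(tier)
  flair <- render(levels$flair)
  t2 <- render(levels$t2)
  if (noise_sd > 0) {
    flair <- flair + array(rnorm(prod(d), 0, noise_sd), d)
    t2 <- t2 + array(rnorm(prod(d), 0, noise_sd), d)
  }
  list(flair = flair, t2 = t2, voxel_dims_mm = wmh_total$voxel_dims_mm)
}
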
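#' Pipeline run configuration
#'
#' Bundles every stage's parameters, the output directory and one global seed
#' into a validated config. The global seed expands deterministically into
#' per-stage seeds (a fixed hash of the stage name), so any stage can be rerun
#' in isolation and reproduce its part of a full run.
#'
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param generator list of [generator_config()] arguments for the simulate
#'   stage (ignored when `cohort_dir` points at existing inputs).
#' @param cohort_dir optional directory of pre-existing inputs (as written by
#'   [write_cohort_dataset()]); must exist if given.
#' @param stages character vector of stages to run, in dependency order, from
#'   `c("simulate", "volumes", "stats", "voxelmap", "associate", "report")`.
#' @param min_overlap,alphas voxel-wise testing parameters.
#' @param contrasts list of lists with fields `feature`, `region`, and
#'   optional `hemisphere` / `risk_factor`, turned into [wmh_contrast()]s.
#' @param lambda,epochs association-model parameters.
#' @param response_mode,response_region arguments to [encode_response()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, generator = list(),
                            cohort_dir = NULL,
                            stages = c("simulate", "volumes", "stats",
                                       "voxelmap", "associate", "report"),
                            min_overlap = 2L, alphas = c(0.05, 0.01),
                            contrasts = list(
                              list(feature = "rssi", region = "centrum semiovale"),
                              list(feature = "rssi",
                                   region = "internal/external capsule/lentiform nucleus")
                            ),
                            lambda = 1 / 47, epochs = 50L,
                            response_mode = "location_code",
                            response_region = NULL) {
  known <- c("simulate", "volumes", "stats", "voxelmap", "associate", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (any(alphas <= 0 | alphas >= 1)) abort("alphas must lie in (0, 1).")
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir)) {
    abort(sprintf("cohort_dir does not exist: %s", cohort_dir))
  }
  if (!is.null(cohort_dir) && !file.exists(file.path(cohort_dir, "cohort.csv"))) {
    abort(sprintf("missing cohort CSV: %s", file.path(cohort_dir, "cohort.csv")))
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), generator = generator,
         cohort_dir = cohort_dir, stages = stages, min_overlap = min_overlap,
         alphas = alphas, contrasts = contrasts, lambda = lambda,
         epochs = as.integer(epochs), response_mode = response_mode,
         response_region = response_region),
    class = "pipeline_config"
  )
}

#' Deterministic per-stage seed derivation
#'
#' @param seed global seed.
#' @param stage stage name.
#' @return Integer below 2^31 that is a fixed function of both arguments.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 65011 * 31013 + h * 7919) %% 2147483629) + 1L
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config), give.attr = FALSE)),
             collapse = "\n")
  f <- tempfile()
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order — simulate (or load)
#' the cohort, volumetrics, subject-level statistics, voxel-wise lesion
#' mapping, the voxel association model, and report tables — writing every
#' artifact under `config$out_dir` and recording it with an md5 checksum in a
#' run manifest. A rerun with the same config and seed is bit-identical for
#' all deterministic stages; a stage failure aborts with the failing stage
#' named, retaining earlier outputs.
#'
#' @param config a [pipeline_config()], or the path to a YAML file of its
#'   arguments.
#' @return List with the `manifest` tibble, per-stage results, and the config
#'   hash, invisibly classed `pipeline_run`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, args)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  hash <- config_hash(config)

  record <- function(paths, stage) {
    rel <- sub(paste0("^", normalizePath(config$out_dir), "/?"), "",
               unname(vapply(paths, normalizePath, character(1))))
    manifest[length(manifest) + seq_along(paths)] <<- lapply(seq_along(paths), function(k) {
      tibble(stage = stage, file = rel[k], md5 = unname(tools::md5sum(paths[k])))
    })
  }
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  # --- simulate / load -----------------------------------------------------
  cohort_obj <- in_stage("simulate", {
    if (!is.null(config$cohort_dir)) {
      load_cohort_dataset(config$cohort_dir)
    } else {
      gen_args <- config$generator
      gen_args$seed <- gen_args$seed %||% stage_seed(config$seed, "simulate")
      gen <- do.call(generator_config, gen_args)
      obj <- generate_cohort(gen)
      if ("simulate" %in% config$stages) {
        dir <- file.path(config$out_dir, "inputs")
        write_cohort_dataset(obj, dir)
        record(list.files(dir, recursive = TRUE, full.names = TRUE), "simulate")
      }
      obj
    }
  })
  cohort <- cohort_obj$cohort

  # --- volumes -------------------------------------------------------------
  if ("volumes" %in% config$stages) {
    results$volumes <- in_stage("volumes", {
      vr <- volume_records(cohort)
      ch <- cohort_changes(cohort)
      sum_rssi <- summarize_by_location(cohort, "rssi")
      sum_lac <- summarize_by_location(cohort, "lacunes")
      paths <- c(
        write_table(vr, config$out_dir, "volume_records.csv"),
        write_table(ch, config$out_dir, "wmh_changes.csv"),
        write_table(sum_rssi$summary, config$out_dir, "volumes_by_rssi_location.csv"),
        write_table(sum_lac$summary, config$out_dir, "volumes_by_lacune_location.csv"),
        write_table(sum_rssi$counts, config$out_dir, "rssi_location_counts.csv"),
        write_table(sum_lac$counts, config$out_dir, "lacune_location_counts.csv")
      )
      record(paths, "volumes")
      list(records = vr, changes = ch, rssi = sum_rssi, lacunes = sum_lac)
    })
  }

  # --- subject-level stats -------------------------------------------------
  if ("stats" %in% config$stages) {
    results$stats <- in_stage("stats", {
      dat <- cohort
      dat$wmh_pct <- pct_icv(dat$wmh_total_ml, dat$icv_ml)
      dat$rssi_pct <- pct_icv(dat$rssi_volume_ml, dat$icv_ml)
      dat$rssi_region <- recode_locations(dat, "primary_only")
      ch <- cohort_changes(cohort)
      dat <- dplyr::left_join(dat, ch, by = "subject_id")
      fits <- list(
        lacunes_baseline = fit_wmh_lm(dat, wmh_pct ~ lacune_count + age),
        rssi_baseline = fit_wmh_lm(dat, wmh_pct ~ rssi_pct + lacune_count + age),
        change_rssi = fit_wmh_ancova(
          dat[dat$has_followup, ],
          wmh_change_pct ~ rssi_pct + lacune_count + age
        )
      )
      tab <- purrr::imap_dfr(fits, function(f, nm) {
        dplyr::mutate(tidy(f), model = nm, n_used = f$n_used, .before = 1)
      })
      paths <- write_table(tab, config$out_dir, "model_fits.csv")
      record(paths, "stats")
      list(fits = fits, table = tab)
    })
  }

  # --- voxel-wise mapping --------------------------------------------------
  stack <- NULL
  if (any(c("voxelmap", "associate") %in% config$stages)) {
    stack <- build_mask4d(cohort_obj$masks$wmh_baseline,
                          names(cohort_obj$masks$wmh_baseline))
  }
  if ("voxelmap" %in% config$stages) {
    results$voxelmap <- in_stage("voxelmap", {
      contrasts <- lapply(config$contrasts, function(cs) {
        do.call(wmh_contrast, c(list(cohort = cohort), cs))
      })
      bat <- run_contrast_battery(stack, cohort, contrasts,
                                  alphas = config$alphas,
                                  min_overlap = config$min_overlap)
      paths <- write_table(bat$results, config$out_dir, "voxel_battery.csv")
      for (i in seq_along(bat$maps)) {
        paths <- c(paths, write_statmap(
          bat$maps[[i]],
          file.path(config$out_dir, sprintf("statmap_%02d", i))
        ))
      }
      record(paths, "voxelmap")
      bat
    })
  }

  # --- association model ---------------------------------------------------
  if ("associate" %in% config$stages) {
    results$associate <- in_stage("associate", {
      fu_ids <- names(cohort_obj$masks$wmh_followup)
      if (length(fu_ids) < 2L) abort("need at least two followed-up subjects.")
      evo <- lapply(fu_ids, function(id) {
        evolution_mask(cohort_obj$masks$wmh_baseline[[id]],
                       cohort_obj$masks$wmh_followup[[id]])
      })
      names(evo) <- fu_ids
      union_mask <- Reduce(`|`, lapply(evo, function(e) e$codes > 0L))
      feats <- build_change_features(evo, union_mask)
      sub <- cohort[match(fu_ids, cohort$subject_id), ]
      y <- encode_response(sub, config$response_mode, config$response_region)
      amap <- fit_sgd_ridge(feats, y, covariates = cbind(age = sub$age),
                            lambda = config$lambda, epochs = config$epochs,
                            seed = stage_seed(config$seed, "associate"))
      disp <- rescale_for_display(amap, 0.5)
      paths <- c(
        write_assoc_vol(amap$positive, amap$voxel_dims_mm,
                        file.path(config$out_dir, "association_positive.nii.gz")),
        write_assoc_vol(amap$negative, amap$voxel_dims_mm,
                        file.path(config$out_dir, "association_negative.nii.gz")),
        write_assoc_vol(disp$positive, amap$voxel_dims_mm,
                        file.path(config$out_dir, "association_positive_display.nii.gz")),
        write_assoc_vol(disp$negative, amap$voxel_dims_mm,
                        file.path(config$out_dir, "association_negative_display.nii.gz")),
        write_table(amap$loss_log, config$out_dir, "association_fit_log.csv")
      )
      record(paths, "associate")
      amap
    })
  }

  # --- report --------------------------------------------------------------
  if ("report" %in% config$stages) {
    results$report <- in_stage("report", {
      demo <- cohort_summary(cohort)
      box <- boxplot_summaries(cohort)
      paths <- c(write_table(demo, config$out_dir, "sample_characteristics.csv"),
                 write_table(box, config$out_dir, "boxplot_summaries.csv"))
      record(paths, "report")
      list(characteristics = demo, boxplots = box)
    })
  }

  manifest_tbl <- dplyr::bind_rows(manifest)
  manifest_tbl$config_hash <- hash
  readr::write_csv(manifest_tbl, file.path(config$out_dir, "manifest.csv"),
                   progress = FALSE)
  cfg_out <- unclass(config)
  cfg_out$contrasts <- NULL  # re-serialised below in plain form
  yaml::write_yaml(
    c(cfg_out, list(contrasts = config$contrasts, config_hash = hash)),
    file.path(config$out_dir, "run_config.yaml")
  )
  invisible(structure(
    list(manifest = manifest_tbl, results = results, config_hash = hash),
    class = "pipeline_run"
  ))
}

write_table <- function(x, dir, name) {
  p <- file.path(dir, name)
  readr::write_csv(x, p, progress = FALSE)
  p
}

write_assoc_vol <- function(arr, voxel_dims_mm, path) {
  img <- RNifti::asNifti(array(as.double(arr), dim(arr)))
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::writeNifti(img, path)
  path
}

#' Load a cohort dataset from disk
#'
#' Inverse of [write_cohort_dataset()]: reads the cohort CSV and all mask
#' directories back into a `wmh_cohort`-shaped object.
#'
#' @param dir dataset directory.
#' @return List with `cohort` and `masks`, classed `wmh_cohort`.
#' @export
load_cohort_dataset <- function(dir) {
  cohort <- read_cohort(file.path(dir, "cohort.csv"))
  masks <- list()
  for (kind in c("wmh_baseline", "wmh_intense", "wmh_followup", "rssi", "old_lesion")) {
    kd <- file.path(dir, kind)
    masks[[kind]] <- list()
    if (dir.exists(kd)) {
      files <- list.files(kd, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
      for (f in files) {
        id <- sub("\\.nii(\\.gz)?$", "", basename(f))
        masks[[kind]][[id]] <- read_mask(f)
      }
    }
  }
  structure(list(cohort = cohort, masks = masks, template = NULL, config = NULL),
            class = "wmh_cohort")
}

cohort_summary <- function(cohort) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  row <- function(variable, value) tibble(variable = variable, value = value)
  dplyr::bind_rows(
    row("n", n),
    row("age_mean", mean(cohort$age)),
    row("age_sd", sd(cohort$age)),
    row("male_fraction", mean(cohort$sex == "male")),
    row("icv_mean_ml", mean(cohort$icv_ml)),
    row("icv_sd_ml", sd(cohort$icv_ml)),
    row("diabetes_fraction", mean(cohort$diabetes)),
    row("hypertension_fraction", mean(cohort$hypertension)),
    row("hyperlipidemia_fraction", mean(cohort$hyperlipidemia)),
    row("current_smoker_fraction", mean(cohort$smoking == "current")),
    row("recent_smoker_fraction", mean(cohort$smoking == "recent")),
    row("ex_smoker_fraction", mean(cohort$smoking == "ex")),
    row("never_smoker_fraction", mean(cohort$smoking == "never")),
    row("rssi_fraction", mean(cohort$rssi_volume_ml > 0)),
    row("lacune_fraction", mean(cohort$lacune_count > 0)),
    row("followup_fraction", mean(cohort$has_followup)),
    row("wmh_total_median_ml", median(cohort$wmh_total_ml))
  )
}

boxplot_summaries <- function(cohort) {
  cohort <- validate_cohort(cohort)
  cohort$rssi_region <- recode_locations(cohort, "primary_only")
  vr <- volume_records(cohort)
  vr <- dplyr::left_join(vr, cohort[, c("subject_id", "rssi_region")],
                         by = "subject_id")
  vr |>
    tidyr::pivot_longer(c("wmh_total_ml", "rssi_ml", "old_lesion_ml"),
                        names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$rssi_region, .data$timepoint, .data$measure) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value),
      q1 = quantile(.data$value, 0.25, names = FALSE),
      q3 = quantile(.data$value, 0.75, names = FALSE),
      whisker_low = min(.data$value), whisker_high = max(.data$value),
      .groups = "drop"
    )
}
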
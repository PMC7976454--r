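#' Mask volume in millilitres
#'
#' Count of lesioned voxels times the voxel volume (mm^3) divided by 1000.
#'
#' @param mask a [lesion_mask].
#' @return Volume in ml.
#' @examples
#' m <- lesion_mask(array(1L, c(10, 10, 1)), voxel_dims_mm = c(2, 2, 2))
#' mask_volume_ml(m)  # 100 voxels x 8 mm^3 = 0.8 ml
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$values) * voxel_volume_ml(mask$voxel_dims_mm)
}

#' Normalise a volume by intracranial volume
#'
#' @param volume_ml lesion volume in ml (>= 0).
#' @param icv_ml intracranial volume in ml (> 0).
#' @return `100 * volume_ml / icv_ml`, the volume as %ICV.
#' @export
pct_icv <- function(volume_ml, icv_ml) {
  if (any(!is.finite(icv_ml) | icv_ml <= 0)) abort("`icv_ml` must be > 0.")
  if (any(volume_ml < 0)) abort("`volume_ml` must be >= 0.")
  100 * volume_ml / icv_ml
}

#' Ternary WMH evolution map between two timepoints
#'
#' Combines baseline and follow-up binary WMH masks into one coded field:
#' 0 = never lesioned, 1 = regressed (baseline only), 2 = stable (both),
#' 3 = progressed (follow-up only). The coding conserves volume exactly:
#' stable + progressed re-assembles the follow-up mask and stable + regressed
#' the baseline mask.
#'
#' @param baseline,followup grid-congruent [lesion_mask] objects.
#' @return An `evolution_map` with fields `codes` (3D integer array) and
#'   `voxel_dims_mm`.
#' @export
evolution_mask <- function(baseline, followup) {
  stopifnot(inherits(baseline, "lesion_mask"), inherits(followup, "lesion_mask"))
  stop_if_incongruent(baseline, followup, "baseline and follow-up masks")
  b <- baseline$values > 0
  f <- followup$values > 0
  codes <- array(0L, dim(b))
  codes[b & !f] <- 1L
  codes[b & f] <- 2L
  codes[!b & f] <- 3L
  structure(list(codes = codes, voxel_dims_mm = baseline$voxel_dims_mm,
                 space_label = baseline$space_label),
            class = "evolution_map")
}

#' @export
print.evolution_map <- function(x, ...) {
  tab <- evolution_volumes(x)
  cat("<evolution_map>\n")
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Voxel counts and volumes per evolution code
#'
#' @param evo an `evolution_map` from [evolution_mask()].
#' @return Tibble with one row per fate (`never`, `regressed`, `stable`,
#'   `progressed`): voxel count and ml.
#' @export
evolution_volumes <- function(evo) {
  stopifnot(inherits(evo, "evolution_map"))
  vv <- voxel_volume_ml(evo$voxel_dims_mm)
  labels <- c("never", "regressed", "stable", "progressed")
  n <- vapply(0:3, function(k) sum(evo$codes == k), numeric(1))
  tibble(code = 0:3, fate = labels, n_voxels = as.integer(n),
         volume_ml = n * vv)
}

#' Extract the mask for a set of evolution codes
#'
#' @param evo an `evolution_map`.
#' @param codes integer codes to include (e.g. `c(2, 3)` for the follow-up
#'   mask, `c(1, 2)` for the baseline mask).
#' @return A [lesion_mask].
#' @export
evolution_submask <- function(evo, codes) {
  stopifnot(inherits(evo, "evolution_map"))
  lesion_mask(array(as.integer(evo$codes %in% codes), dim(evo$codes)),
              evo$voxel_dims_mm, evo$space_label %||% "template")
}

#' Per-subject volume records in long form
#'
#' Unrolls a cohort table into one row per subject and timepoint carrying the
#' tiered WMH, RSSI and old-lesion volumes in ml and as %ICV.
#'
#' @param cohort cohort tibble (see [validate_cohort()]).
#' @return Tibble with columns `subject_id`, `timepoint` (`baseline` /
#'   `year1`), the `*_ml` volume fields, `icv_ml` and the matching `*_pct`
#'   fields.
#' @export
volume_records <- function(cohort) {
  cohort <- validate_cohort(cohort)
  base <- tibble(
    subject_id = cohort$subject_id, timepoint = "baseline",
    wmh_total_ml = cohort$wmh_total_ml,
    wmh_intense_ml = cohort$wmh_intense_ml,
    wmh_less_intense_ml = cohort$wmh_less_intense_ml,
    rssi_ml = cohort$rssi_volume_ml,
    old_lesion_ml = cohort$old_lesion_volume_ml,
    icv_ml = cohort$icv_ml
  )
  y1 <- tibble(
    subject_id = cohort$subject_id, timepoint = "year1",
    wmh_total_ml = cohort$wmh_total_y1_ml,
    wmh_intense_ml = cohort$wmh_intense_y1_ml,
    wmh_less_intense_ml = cohort$wmh_less_intense_y1_ml,
    rssi_ml = cohort$rssi_volume_ml,
    old_lesion_ml = cohort$old_lesion_volume_ml,
    icv_ml = cohort$icv_ml
  )[cohort$has_followup, ]
  out <- dplyr::bind_rows(base, y1)
  for (col in c("wmh_total", "wmh_intense", "wmh_less_intense", "rssi", "old_lesion")) {
    out[[paste0(col, "_pct")]] <- pct_icv(
      ifelse(is.na(out[[paste0(col, "_ml")]]), 0, out[[paste0(col, "_ml")]]),
      out$icv_ml
    )
    out[[paste0(col, "_pct")]][is.na(out[[paste0(col, "_ml")]])] <- NA_real_
  }
  out
}

#' Signed WMH volume change between two volume records
#'
#' Follow-up minus baseline; sign is preserved, so WMH regression yields a
#' negative change.
#'
#' @param record_base,record_y1 one-row tibbles (or lists) for the same
#'   subject at `baseline` and `year1`, as produced by [volume_records()].
#' @return Tibble with the subject id and the change in ml and %ICV.
#' @export
change_volume <- function(record_base, record_y1) {
  if (!identical(record_base$subject_id, record_y1$subject_id)) {
    abort("records belong to different subjects.")
  }
  d_ml <- record_y1$wmh_total_ml - record_base$wmh_total_ml
  tibble(
    subject_id = record_base$subject_id,
    wmh_change_ml = d_ml,
    wmh_change_pct = pct_icv(abs(d_ml), record_base$icv_ml) * sign(d_ml)
  )
}

#' WMH change for every followed-up subject
#'
#' @param cohort cohort tibble.
#' @return Tibble `subject_id`, `wmh_change_ml`, `wmh_change_pct` for subjects
#'   with follow-up data; no imputation is performed for the rest.
#' @export
cohort_changes <- function(cohort) {
  cohort <- validate_cohort(cohort)
  fu <- cohort[cohort$has_followup & !is.na(cohort$wmh_total_y1_ml), ]
  d_ml <- fu$wmh_total_y1_ml - fu$wmh_total_ml
  tibble(
    subject_id = fu$subject_id,
    wmh_change_ml = d_ml,
    wmh_change_pct = 100 * d_ml / fu$icv_ml
  )
}

#' Median (Q1, Q3) volume summaries per lesion location
#'
#' Mirrors the cohort-description tables: per anatomical region (of the RSSI
#' or of the lacunes) and timepoint, the median and interquartile range of
#' each volume class, plus per-region/hemisphere feature counts. Quantiles use
#' linear interpolation between order statistics (R type 7), the package-wide
#' convention. Groups smaller than `min_n` are emitted but flagged
#' `descriptive_only`.
#'
#' @param cohort cohort tibble.
#' @param feature `"rssi"` or `"lacunes"`: which lesion's location defines the
#'   grouping.
#' @param min_n group-size floor below which summaries are flagged.
#' @return List of two tibbles: `summary` (feature, region, timepoint,
#'   measure, n, median, q1, q3, descriptive_only) and `counts` (region,
#'   hemisphere, n_features, n_patients).
#' @export
summarize_by_location <- function(cohort, feature = c("rssi", "lacunes"),
                                  min_n = 5L) {
  feature <- match.arg(feature)
  cohort <- validate_cohort(cohort)
  col <- if (feature == "rssi") "rssi_locations" else "lacune_locations"
  locs <- parse_locations(cohort[[col]])

  counts <- purrr::map2_dfr(locs, cohort$subject_id, function(l, id) {
    if (nrow(l) == 0) return(NULL)
    l$subject_id <- id
    l
  })
  count_tab <- if (nrow(counts)) {
    counts |>
      dplyr::group_by(.data$region, .data$hemisphere) |>
      dplyr::summarise(n_features = dplyr::n(),
                       n_patients = dplyr::n_distinct(.data$subject_id),
                       .groups = "drop")
  } else {
    tibble(region = character(), hemisphere = character(),
           n_features = integer(), n_patients = integer())
  }

  vr <- volume_records(cohort)
  subj_regions <- purrr::map2_dfr(locs, cohort$subject_id, function(l, id) {
    if (nrow(l) == 0) return(NULL)
    tibble(subject_id = id, region = unique(l$region))
  })
  measures <- c("wmh_total_ml", "wmh_intense_ml", "wmh_less_intense_ml",
                "rssi_ml", "old_lesion_ml",
                "wmh_total_pct", "wmh_intense_pct", "wmh_less_intense_pct",
                "rssi_pct", "old_lesion_pct")
  summary <- subj_regions |>
    dplyr::inner_join(vr, by = "subject_id", relationship = "many-to-many") |>
    tidyr::pivot_longer(dplyr::all_of(measures),
                        names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$region, .data$timepoint, .data$measure) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value),
      q1 = quantile(.data$value, 0.25, names = FALSE, type = 7),
      q3 = quantile(.data$value, 0.75, names = FALSE, type = 7),
      .groups = "drop"
    ) |>
    dplyr::mutate(feature = feature, descriptive_only = .data$n < min_n) |>
    dplyr::relocate("feature")
  list(summary = summary, counts = count_tab)
}
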
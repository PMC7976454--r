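#' Read a binary lesion mask from NIfTI
#'
#' Loads a 3D NIfTI volume, normalises its orientation to the RAS-like
#' canonical axis order, and binarises it with the rule `|v| > tol`. The
#' tolerance default (0.5) accommodates masks that arrive as interpolated
#' floats after resampling. Volumes whose transform involves more than axis
#' permutations and flips are rejected: inputs are assumed already
#' co-registered to a common grid, so anything else signals a registration
#' problem that this package deliberately does not repair.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param tol binarisation threshold applied to absolute values.
#' @param space_label space token to stamp on the mask.
#' @return A [lesion_mask].
#' @export
read_mask <- function(path, tol = 0.5, space_label = "template") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    abort(sprintf("expected a 3D volume, got %dD: %s", length(dim(img)), path))
  }
  check_axis_aligned(img, path)
  img <- normalise_orientation(img)
  arr <- as.array(img)
  if (all(is.na(arr))) abort(sprintf("all-NaN volume: %s", path))
  arr[is.na(arr)] <- 0
  vd <- RNifti::pixdim(img)[1:3]
  lesion_mask(array(as.integer(abs(arr) > tol), dim(arr)),
              voxel_dims_mm = vd, space_label = space_label)
}

check_axis_aligned <- function(img, path) {
  x <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(x, "try-error")) return(invisible(TRUE))
  R <- x[1:3, 1:3]
  ok <- all(vapply(1:3, function(i) {
    r <- abs(R[i, ])
    m <- max(r)
    m > 0 && sum(r > 1e-4 * m) == 1L
  }, logical(1)))
  if (!ok) {
    abort(sprintf(
      "non-axis-aligned transform in %s; inputs must be pre-registered to the common grid.",
      path
    ))
  }
  invisible(TRUE)
}

normalise_orientation <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0 && hdr$sform_code == 0) return(img)  # no xform: as-is
  res <- try(suppressWarnings({
    tmp <- img
    RNifti::orientation(tmp) <- "LAS"
    tmp
  }), silent = TRUE)
  if (inherits(res, "try-error")) img else res
}

#' Write a lesion mask to NIfTI
#'
#' @param mask a [lesion_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  img <- RNifti::asNifti(array(as.double(mask$values), dim(mask$values)))
  RNifti::pixdim(img) <- mask$voxel_dims_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Stack congruent lesion masks into a 4D array
#'
#' The subject-aligned 4D stack (three spatial axes plus one subject axis) is
#' the unit all voxel-wise statistics operate on. All masks must be
#' grid-congruent; subject ids must be unique and aligned with `masks`.
#'
#' @param masks list of [lesion_mask] objects.
#' @param subject_ids character vector, one id per mask.
#' @return A `mask_stack` object with fields `stack` (4D 0/1 array),
#'   `subject_ids`, `voxel_dims_mm` and `space_label`.
#' @export
build_mask4d <- function(masks, subject_ids) {
  if (length(masks) < 1L) abort("need at least one mask.")
  if (length(masks) != length(subject_ids)) {
    abort("`masks` and `subject_ids` must have the same length.")
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) abort("duplicate subject ids.")
  ref <- masks[[1]]
  for (i in seq_along(masks)) {
    if (!inherits(masks[[i]], "lesion_mask")) abort("all elements must be lesion_mask objects.")
    stop_if_incongruent(ref, masks[[i]], sprintf("masks 1 and %d", i))
  }
  d <- dim(ref$values)
  stack <- array(0L, c(d, length(masks)))
  for (i in seq_along(masks)) stack[, , , i] <- masks[[i]]$values
  structure(
    list(
      stack = stack, subject_ids = subject_ids,
      voxel_dims_mm = ref$voxel_dims_mm, space_label = ref$space_label
    ),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<mask_stack> %d subjects on %s grid (%s mm voxels)\n",
              d[4], paste(d[1:3], collapse = "x"),
              paste(signif(x$voxel_dims_mm, 4), collapse = "x")))
  invisible(x)
}

#' Per-voxel lesion frequency map of a mask stack
#'
#' @param stack a `mask_stack` from [build_mask4d()].
#' @return 3D integer array counting lesioned subjects at each voxel.
#' @export
frequency_map <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  rowSums(stack$stack, dims = 3L)
}

cohort_required_cols <- function() {
  c(
    "subject_id", "age", "sex", "diabetes", "hypertension", "hyperlipidemia",
    "smoking", "rssi_locations", "lacune_count", "lacune_locations",
    "rssi_volume_ml", "old_lesion_volume_ml", "icv_ml", "has_followup"
  )
}

#' Validate a cohort table
#'
#' Checks the per-subject clinical record: required columns, the location-code
#' vocabulary, positive intracranial volume, agreement between `lacune_count`
#' and the number of lacune location codes, and the RSSI volume/location
#' consistency rule (volume zero if and only if no RSSI code).
#'
#' @param cohort a data frame.
#' @return The cohort as a tibble, invisibly classed for printing.
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(cohort_required_cols(), names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cohort$subject_id)) abort("duplicate subject_id values.")
  bad_icv <- which(!is.finite(cohort$icv_ml) | cohort$icv_ml <= 0)
  if (length(bad_icv)) {
    abort(sprintf("non-positive icv_ml for subject(s): %s",
                  paste(cohort$subject_id[bad_icv], collapse = ", ")))
  }
  bad_smoke <- setdiff(unique(cohort$smoking), c("current", "recent", "ex", "never"))
  if (length(bad_smoke)) {
    abort(sprintf("unknown smoking level(s): %s", paste(bad_smoke, collapse = ", ")))
  }
  rssi_loc <- parse_locations(cohort$rssi_locations)   # errors on unknown codes
  lac_loc <- parse_locations(cohort$lacune_locations)
  n_lac <- vapply(lac_loc, nrow, integer(1))
  bad_lac <- which(n_lac != cohort$lacune_count)
  if (length(bad_lac)) {
    abort(sprintf("lacune_count disagrees with lacune_locations for subject(s): %s",
                  paste(cohort$subject_id[bad_lac], collapse = ", ")))
  }
  n_rssi <- vapply(rssi_loc, nrow, integer(1))
  bad_rssi <- which((cohort$rssi_volume_ml > 0) != (n_rssi > 0))
  if (length(bad_rssi)) {
    abort(sprintf("rssi_volume_ml / rssi_locations inconsistent for subject(s): %s",
                  paste(cohort$subject_id[bad_rssi], collapse = ", ")))
  }
  cohort
}

#' Read and write cohort tables as CSV
#'
#' `write_cohort()` then `read_cohort()` round-trips all fields exactly
#' (numeric values are written in shortest round-trippable form).
#'
#' @param path CSV file path.
#' @param cohort cohort tibble (validated on write and on read).
#' @return `read_cohort()` returns the validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      smoking = readr::col_character(),
      rssi_locations = readr::col_character(),
      lacune_locations = readr::col_character(),
      lacune_count = readr::col_integer(),
      diabetes = readr::col_logical(),
      hypertension = readr::col_logical(),
      hyperlipidemia = readr::col_logical(),
      has_followup = readr::col_logical(),
      .default = readr::col_double()
    ),
    na = "NA", progress = FALSE
  )
  for (col in c("rssi_locations", "lacune_locations")) {
    cohort[[col]][is.na(cohort[[col]])] <- ""
  }
  validate_cohort(cohort)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a voxel statistic map to NIfTI files
#'
#' Emits the statistic (`H`), p-value (`P`) and each FDR decision field as
#' separate volumes sharing the prefix.
#'
#' @param map a `voxel_stat_map` from [voxelwise_kw()].
#' @param prefix output path prefix; files are `<prefix>_H.nii.gz` etc.
#' @return Written paths, invisibly.
#' @export
write_statmap <- function(map, prefix) {
  stopifnot(inherits(map, "voxel_stat_map"))
  write_vol <- function(arr, suffix) {
    a <- arr
    a[is.na(a)] <- 0
    img <- RNifti::asNifti(array(as.double(a), dim(a)))
    RNifti::pixdim(img) <- map$voxel_dims_mm
    p <- paste0(prefix, "_", suffix, ".nii.gz")
    RNifti::writeNifti(img, p)
    p
  }
  paths <- c(
    write_vol(map$H, "H"),
    write_vol(map$P, "P"),
    write_vol(array(as.double(map$tested), dim(map$tested)), "tested")
  )
  for (nm in names(map$sig)) {
    paths <- c(paths, write_vol(array(as.double(map$sig[[nm]]), dim(map$tested)),
                                paste0("sig", gsub("[^0-9]", "", nm))))
  }
  invisible(paths)
}
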
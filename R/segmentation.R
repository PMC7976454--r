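#' Fuse two structural channels into a red-green intensity image
#'
#' Each channel is robustly rescaled to \[0, 1\] using its 1st-99th percentile
#' window, and the fused scalar is the voxel-wise minimum of the two channels:
#' a WMH voxel must be bright on both sequences. This is a deliberately
#' simplified conjunction rule for red-green colour-space fusion segmentation,
#' not a faithful port of any particular tool.
#'
#' @param seq_a,seq_b congruent 3D intensity arrays (e.g. FLAIR-like and
#'   T2-like).
#' @param voxel_dims_mm voxel size in mm.
#' @param probs percentile window used for robust rescaling.
#' @return A `fusion_image` with fields `red`, `green`, `fused` (all in
#'   \[0, 1\]) and `voxel_dims_mm`.
#' @export
rg_fuse <- function(seq_a, seq_b, voxel_dims_mm = c(1, 1, 1),
                    probs = c(0.01, 0.99)) {
  if (!identical(dim(seq_a), dim(seq_b))) abort("channel grids differ.")
  if (length(dim(seq_a)) != 3L) abort("channels must be 3D arrays.")
  check_voxel_dims(voxel_dims_mm)
  red <- robust_rescale(seq_a, probs)
  green <- robust_rescale(seq_b, probs)
  structure(
    list(red = red, green = green, fused = pmin(red, green),
         voxel_dims_mm = as.numeric(voxel_dims_mm)),
    class = "fusion_image"
  )
}

robust_rescale <- function(v, probs = c(0.01, 0.99)) {
  q <- quantile(v, probs, na.rm = TRUE, names = FALSE)
  if (q[2] <= q[1]) abort("constant (zero-range) channel cannot be rescaled.")
  out <- (v - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Threshold a fused image into tiered WMH masks
#'
#' `total` is the fused image at or above `low_thr`; `intense` the part at or
#' above `high_thr`; `less_intense` their set difference. The tiers always
#' partition the total mask.
#'
#' @param fusion a `fusion_image` from [rg_fuse()].
#' @param low_thr,high_thr thresholds with `0 <= low_thr < high_thr <= 1`.
#' @return A `tiered_wmh` list of [lesion_mask] objects `intense`,
#'   `less_intense` and `total`.
#' @export
segment_wmh <- function(fusion, low_thr, high_thr) {
  stopifnot(inherits(fusion, "fusion_image"))
  if (!(low_thr >= 0 && low_thr < high_thr && high_thr <= 1)) {
    abort("need 0 <= low_thr < high_thr <= 1.")
  }
  s <- fusion$fused
  total <- s >= low_thr
  intense <- s >= high_thr
  mk <- function(a) lesion_mask(array(as.integer(a), dim(a)), fusion$voxel_dims_mm)
  structure(
    list(intense = mk(intense), less_intense = mk(total & !intense),
         total = mk(total)),
    class = "tiered_wmh"
  )
}

#' @export
print.tiered_wmh <- function(x, ...) {
  cat(sprintf("<tiered_wmh> total %.3f ml = intense %.3f ml + less intense %.3f ml\n",
              mask_volume_ml(x$total), mask_volume_ml(x$intense),
              mask_volume_ml(x$less_intense)))
  invisible(x)
}

#' Seeded region growing
#'
#' Returns the 26-connected component of `{image >= intensity_floor}` that
#' contains the seed voxel. If the seed itself is below the floor the result
#' is an empty mask with attribute `empty = TRUE` (flagged, not an error).
#'
#' @param image 3D intensity array, finite at the seed.
#' @param seed_voxel integer length-3 voxel coordinate (1-based).
#' @param intensity_floor inclusion threshold.
#' @param voxel_dims_mm voxel size in mm.
#' @return A [lesion_mask]; attribute `empty` is TRUE when nothing grew.
#' @export
region_grow <- function(image, seed_voxel, intensity_floor,
                        voxel_dims_mm = c(1, 1, 1)) {
  d <- dim(image)
  if (length(d) != 3L) abort("`image` must be a 3D array.")
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > d)) {
    abort("seed voxel out of bounds.")
  }
  sv <- image[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  if (!is.finite(sv)) abort("image is not finite at the seed.")
  candidate <- array(is.finite(image) & image >= intensity_floor, d)
  out <- array(FALSE, d)
  if (!candidate[seed_voxel[1], seed_voxel[2], seed_voxel[3]]) {
    m <- lesion_mask(array(0L, d), voxel_dims_mm)
    attr(m, "empty") <- TRUE
    return(m)
  }
  frontier <- array(FALSE, d)
  frontier[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
  out <- frontier
  repeat {
    nxt <- dilate_box(frontier) & candidate & !out
    if (!any(nxt)) break
    out <- out | nxt
    frontier <- nxt
  }
  m <- lesion_mask(array(as.integer(out), d), voxel_dims_mm)
  attr(m, "empty") <- !any(out)
  m
}
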
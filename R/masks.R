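#' Binary lesion masks on a common grid
#'
#' A `lesion_mask` is a subject's binary lesion map on a 3D grid with physical
#' voxel dimensions in millimetres. All voxel-wise machinery in the package
#' assumes masks are already co-registered to one common space; congruence
#' (equal grid dimensions, voxel sizes and space label) is enforced whenever
#' masks are combined, and violations are errors rather than resampling.
#'
#' @param values 3D array (logical, or numeric in \{0, 1\}).
#' @param voxel_dims_mm positive numeric length 3, voxel edge lengths in mm.
#' @param space_label token naming the common space the mask lives in.
#' @return A `lesion_mask` object.
#' @examples
#' m <- lesion_mask(array(0, c(4, 4, 4)), voxel_dims_mm = c(1, 1, 1))
#' mask_volume_ml(m)
#' @export
lesion_mask <- function(values, voxel_dims_mm = c(1, 1, 1),
                        space_label = "template") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  v <- as.vector(values)
  if (anyNA(v)) abort("mask values must not contain NA.")
  if (!all(v %in% c(0, 1))) abort("mask values must be binary (0/1).")
  check_voxel_dims(voxel_dims_mm)
  structure(
    list(
      values = array(as.integer(v), dim(values)),
      voxel_dims_mm = as.numeric(voxel_dims_mm),
      space_label = as.character(space_label)
    ),
    class = "lesion_mask"
  )
}

check_voxel_dims <- function(voxel_dims_mm) {
  if (length(voxel_dims_mm) != 3L || !is.numeric(voxel_dims_mm) ||
      any(!is.finite(voxel_dims_mm)) || any(voxel_dims_mm <= 0)) {
    abort("`voxel_dims_mm` must be 3 strictly positive numbers.")
  }
  invisible(voxel_dims_mm)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask> %s grid, %s mm voxels, space '%s', %d voxels on (%.3f ml)\n",
    paste(dim(x$values), collapse = "x"),
    paste(signif(x$voxel_dims_mm, 4), collapse = "x"),
    x$space_label, sum(x$values), mask_volume_ml(x)
  ))
  invisible(x)
}

#' @export
as.array.lesion_mask <- function(x, ...) x$values

#' @export
dim.lesion_mask <- function(x) dim(x$values)

voxel_volume_ml <- function(voxel_dims_mm) prod(voxel_dims_mm) / 1000

masks_congruent <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$voxel_dims_mm - b$voxel_dims_mm) <= tol) &&
    identical(a$space_label, b$space_label)
}

stop_if_incongruent <- function(a, b, what = "masks") {
  if (!masks_congruent(a, b)) {
    abort(sprintf(
      "%s are not grid-congruent (dims %s vs %s; voxel %s vs %s; space '%s' vs '%s').",
      what,
      paste(dim(a$values), collapse = "x"), paste(dim(b$values), collapse = "x"),
      paste(signif(a$voxel_dims_mm, 4), collapse = "x"),
      paste(signif(b$voxel_dims_mm, 4), collapse = "x"),
      a$space_label, b$space_label
    ))
  }
  invisible(TRUE)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b grid-congruent [lesion_mask] objects (or logical arrays).
#' @return Dice coefficient in \[0, 1\]; defined as 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  av <- if (inherits(a, "lesion_mask")) a$values else a
  bv <- if (inherits(b, "lesion_mask")) b$values else b
  if (!identical(dim(av), dim(bv))) abort("masks must share a grid.")
  sa <- sum(av != 0); sb <- sum(bv != 0)
  if (sa + sb == 0) return(1)
  2 * sum(av != 0 & bv != 0) / (sa + sb)
}

# --- morphology on logical 3D arrays (zero-padded) -------------------------

shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (s[k] >= 0) {
      if (s[k] >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - s[k])
      dst[[k]] <- seq_len(d[k] - s[k]) + s[k]
    } else {
      if (-s[k] >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] + s[k]) - s[k]
      dst[[k]] <- seq_len(d[k] + s[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

offsets6 <- rbind(
  c(1, 0, 0), c(-1, 0, 0),
  c(0, 1, 0), c(0, -1, 0),
  c(0, 0, 1), c(0, 0, -1)
)

dilate_cross <- function(a) {
  out <- a
  for (i in seq_len(nrow(offsets6))) out <- out | shift3(a, offsets6[i, ])
  out
}

erode_cross <- function(a) {
  out <- a
  for (i in seq_len(nrow(offsets6))) out <- out & shift3(a, offsets6[i, ])
  out
}

close_cross <- function(a) erode_cross(dilate_cross(a))

# 3x3x3 box dilation/erosion (separable); box dilation minus the input is the
# 26-connected neighbourhood ring.
dilate_axis <- function(a, axis) {
  s <- c(0, 0, 0); s[axis] <- 1
  sm <- c(0, 0, 0); sm[axis] <- -1
  a | shift3(a, s) | shift3(a, sm)
}

dilate_box <- function(a) dilate_axis(dilate_axis(dilate_axis(a, 1), 2), 3)

ring26 <- function(a) dilate_box(a) & !a
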
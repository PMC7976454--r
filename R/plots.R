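slice_tibble <- function(arr, slice, value_name = "value") {
  d <- dim(arr)
  z <- slice %||% ceiling(d[3] / 2)
  plane <- arr[, , z]
  tibble(
    x = rep(seq_len(d[1]), times = d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    !!value_name := as.vector(plane)
  )
}

#' Plot an axial slice of a WMH evolution map
#'
#' @param object an `evolution_map`.
#' @param slice axial (third-axis) slice index; defaults to the mid-slice.
#' @param ... unused.
#' @return A ggplot object colouring voxel fate (regressed / stable /
#'   progressed).
#' @method autoplot evolution_map
#' @export
autoplot.evolution_map <- function(object, slice = NULL, ...) {
  df <- slice_tibble(object$codes, slice, "code")
  df$fate <- factor(c("never", "regressed", "stable", "progressed")[df$code + 1],
                    levels = c("never", "regressed", "stable", "progressed"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$fate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(never = "grey95", regressed = "steelblue",
                                          stable = "grey40", progressed = "firebrick")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "WMH evolution", fill = "fate") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a voxel statistic map
#'
#' @param object a `voxel_stat_map`.
#' @param what `"H"`, `"P"`, or an FDR level (e.g. `"0.05"`) whose decision
#'   field to show.
#' @param slice axial slice index; defaults to the mid-slice.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot voxel_stat_map
#' @export
autoplot.voxel_stat_map <- function(object, what = "H", slice = NULL, ...) {
  arr <- if (what %in% c("H", "P")) {
    object[[what]]
  } else if (what %in% names(object$sig)) {
    array(as.double(object$sig[[what]]), dim(object$tested))
  } else {
    abort(sprintf("unknown field '%s'.", what))
  }
  df <- slice_tibble(arr, slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey95") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$label, fill = what) +
    ggplot2::theme_minimal()
}

#' Plot signed association maps
#'
#' Shows the display-rescaled positive (cyan) and negative (red) association
#' fields of one axial slice side by side.
#'
#' @param object an `association_map`.
#' @param slice axial slice index; defaults to the mid-slice.
#' @param fraction rescaling fraction passed to [rescale_for_display()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot association_map
#' @export
autoplot.association_map <- function(object, slice = NULL, fraction = 0.5, ...) {
  disp <- rescale_for_display(object, fraction)
  dp <- slice_tibble(disp$positive, slice)
  dn <- slice_tibble(disp$negative, slice)
  dp$sign <- "positive"
  dn$sign <- "negative"
  df <- dplyr::bind_rows(dp, dn)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   alpha = .data$value, fill = .data$sign)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(positive = "cyan3", negative = "red3")) +
    ggplot2::facet_wrap(~sign) +
    ggplot2::coord_fixed() +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(title = "voxel association with RSSI location") +
    ggplot2::theme_minimal()
}

#' Box plots of lesion volumes by RSSI location and timepoint
#'
#' @param cohort cohort tibble.
#' @param measure volume column of [volume_records()] to plot.
#' @return A ggplot object with one box per location and timepoint.
#' @export
plot_volumes_by_location <- function(cohort, measure = "wmh_total_ml") {
  cohort <- validate_cohort(cohort)
  cohort$rssi_region <- recode_locations(cohort, "primary_only")
  vr <- dplyr::left_join(volume_records(cohort),
                         cohort[, c("subject_id", "rssi_region")],
                         by = "subject_id")
  vr <- vr[!is.na(vr[[measure]]) & vr$rssi_region != "none", ]
  ggplot2::ggplot(vr, ggplot2::aes(.data$rssi_region, .data[[measure]],
                                   fill = .data$timepoint)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = measure, fill = NULL) +
    ggplot2::theme_minimal()
}
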
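# closed-form tie-corrected two-group Kruskal-Wallis on binary indicators,
# vectorised over voxels: at a voxel, `a` of n1 target and `b` of n2
# comparison subjects are lesioned.
kw_binary_counts <- function(a, b, n1, n2) {
  N <- n1 + n2
  m1 <- a + b
  m0 <- N - m1
  r0 <- (m0 + 1) / 2
  r1 <- m0 + (m1 + 1) / 2
  # deviation form (no large-term cancellation): mean ranks vs (N+1)/2
  dev1 <- ((n1 - a) * r0 + a * r1) / n1 - (N + 1) / 2
  dev2 <- ((n2 - b) * r0 + b * r1) / n2 - (N + 1) / 2
  H_raw <- 12 / (N * (N + 1)) * (n1 * dev1^2 + n2 * dev2^2)
  C <- 1 - (m0^3 - m0 + m1^3 - m1) / (N^3 - N)
  H <- ifelse(C > 0, H_raw / C, 0)
  P <- ifelse(C > 0, pchisq(H, df = 1, lower.tail = FALSE), 1)
  list(H = H, P = P)
}

#' Define a group-vs-rest contrast from the cohort table
#'
#' The target group holds subjects with the lesion feature in the named
#' location (optionally restricted to one hemisphere) and, when a risk
#' condition is given, carrying that risk factor; the comparison group holds
#' subjects with the feature elsewhere and, when conditioned, without the risk
#' factor. Subjects in neither group are excluded from that contrast.
#'
#' @param cohort cohort tibble.
#' @param feature `"rssi"` or `"lacunes"`.
#' @param region anatomical region name (see [wmh_regions()]).
#' @param hemisphere optional `"left"` or `"right"`.
#' @param risk_factor optional risk condition: `"hypertension"`,
#'   `"hyperlipidemia"`, `"diabetes"`, or `"smoking"` (current or recent
#'   smokers, the default smoking grouping).
#' @param label optional contrast label.
#' @return A `wmh_contrast` list with `target_ids`, `comparison_ids`, `label`.
#' @export
wmh_contrast <- function(cohort, feature = c("rssi", "lacunes"), region,
                         hemisphere = NULL, risk_factor = NULL, label = NULL) {
  feature <- match.arg(feature)
  cohort <- validate_cohort(cohort)
  if (!region %in% wmh_regions()) abort(sprintf("unknown region: %s", region))
  col <- if (feature == "rssi") "rssi_locations" else "lacune_locations"
  locs <- parse_locations(cohort[[col]])
  in_loc <- vapply(locs, function(l) {
    hit <- l$region == region
    if (!is.null(hemisphere)) hit <- hit & l$hemisphere == hemisphere
    any(hit)
  }, logical(1))
  has_feature <- vapply(locs, nrow, integer(1)) > 0L
  if (is.null(risk_factor)) {
    target <- in_loc
    comparison <- has_feature & !in_loc
  } else {
    has_risk <- if (risk_factor == "smoking") {
      cohort$smoking %in% c("current", "recent")
    } else if (risk_factor %in% c("hypertension", "hyperlipidemia", "diabetes")) {
      cohort[[risk_factor]]
    } else {
      abort(sprintf("unknown risk factor: %s", risk_factor))
    }
    target <- in_loc & has_risk
    comparison <- has_feature & !in_loc & !has_risk
  }
  if (!any(target) || !any(comparison)) {
    abort("both contrast groups must be non-empty.")
  }
  structure(
    list(
      target_ids = cohort$subject_id[target],
      comparison_ids = cohort$subject_id[comparison],
      label = label %||% paste0(
        feature, " in ", region,
        if (!is.null(hemisphere)) paste0(" (", hemisphere, ")") else "",
        if (!is.null(risk_factor)) paste0(", ", risk_factor) else ""
      )
    ),
    class = "wmh_contrast"
  )
}

#' Voxel-wise Kruskal-Wallis comparison of WMH maps
#'
#' At every voxel lesioned in at least `min_overlap` subjects across the two
#' groups, tests whether the binary WMH indicator differs between target and
#' comparison subjects with the tie-corrected Kruskal-Wallis statistic (on 0/1
#' data this reduces to a two-sample rank test). Voxels below the overlap
#' floor are excluded both from testing and from the multiple-testing family,
#' so untestable voxels never inflate the family size.
#'
#' @param stack a `mask_stack` from [build_mask4d()].
#' @param contrast a `wmh_contrast`, or a list with `target_ids` and
#'   `comparison_ids`.
#' @param min_overlap minimum lesioned-subject count for a voxel to enter the
#'   tested family (>= 1).
#' @return A `voxel_stat_map`: 3D fields `H` and `P` (NA outside the tested
#'   family), logical `tested`, group sizes, family size `m`, and (after
#'   [fdr_bh()]) FDR decision fields in `$sig`.
#' @export
voxelwise_kw <- function(stack, contrast, min_overlap = 2L) {
  stopifnot(inherits(stack, "mask_stack"))
  if (min_overlap < 1L) abort("`min_overlap` must be >= 1.")
  tgt <- match(contrast$target_ids, stack$subject_ids)
  cmp <- match(contrast$comparison_ids, stack$subject_ids)
  tgt <- tgt[!is.na(tgt)]
  cmp <- cmp[!is.na(cmp)]
  if (length(intersect(tgt, cmp))) abort("contrast groups overlap.")
  n1 <- length(tgt)
  n2 <- length(cmp)
  if (n1 == 0L || n2 == 0L) abort("both contrast groups must be non-empty in the stack.")
  if (min_overlap > n1 + n2) abort("`min_overlap` exceeds the analyzable sample size.")
  d <- dim(stack$stack)[1:3]
  nvox <- prod(d)
  M <- matrix(stack$stack, nrow = nvox)
  a <- rowSums(M[, tgt, drop = FALSE])
  b <- rowSums(M[, cmp, drop = FALSE])
  tested_v <- (a + b) >= min_overlap
  H <- P <- array(NA_real_, d)
  if (any(tested_v)) {
    kw <- kw_binary_counts(a[tested_v], b[tested_v], n1, n2)
    H[tested_v] <- kw$H
    P[tested_v] <- kw$P
  }
  structure(
    list(
      H = H, P = P, tested = array(tested_v, d), m = sum(tested_v),
      n_target = n1, n_comparison = n2,
      voxel_dims_mm = stack$voxel_dims_mm, sig = list(),
      fdr_info = tibble(alpha = numeric(), m = integer(),
                        n_rejected = integer(), p_cutoff = numeric()),
      label = contrast$label %||% "contrast"
    ),
    class = "voxel_stat_map"
  )
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat(sprintf("<voxel_stat_map> %s: %d vs %d subjects, %d tested voxels\n",
              x$label, x$n_target, x$n_comparison, x$m))
  if (nrow(x$fdr_info)) print(as.data.frame(x$fdr_info), row.names = FALSE)
  invisible(x)
}

alpha_key <- function(alpha) sprintf("%g", alpha)

#' Benjamini-Hochberg FDR correction over the tested voxel family
#'
#' Step-up correction applied to the tested voxels only (the family excludes
#' voxels below the overlap floor). Stores the decision field on the map and
#' records the family size, rejection count and realized p cut-off.
#'
#' @param map a `voxel_stat_map`.
#' @param alpha FDR level in (0, 1).
#' @return The map with an added decision field `sig[[as character alpha]]`
#'   and an updated `fdr_info` row.
#' @export
fdr_bh <- function(map, alpha = 0.05) {
  stopifnot(inherits(map, "voxel_stat_map"))
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  if (map$m < 1L) abort("empty tested family.")
  p <- map$P[map$tested]
  rejected <- p.adjust(p, method = "BH") <= alpha
  sig <- array(FALSE, dim(map$tested))
  sig[map$tested] <- rejected
  map$sig[[alpha_key(alpha)]] <- sig
  map$fdr_info <- dplyr::bind_rows(
    map$fdr_info[map$fdr_info$alpha != alpha, ],
    tibble(alpha = alpha, m = map$m, n_rejected = sum(rejected),
           p_cutoff = if (any(rejected)) max(p[rejected]) else 0)
  )
  map
}

#' Count suprathreshold voxels and convert to millilitres
#'
#' @param map a `voxel_stat_map` on which [fdr_bh()] has been run at `cutoff`.
#' @param cutoff FDR level whose decision field to count (e.g. 0.05 or 0.01).
#' @return Tibble with `n_voxels` and `volume_ml`
#'   (`n_voxels * voxel volume / 1000`).
#' @export
count_significant <- function(map, cutoff) {
  stopifnot(inherits(map, "voxel_stat_map"))
  key <- alpha_key(cutoff)
  if (!key %in% names(map$sig)) {
    abort(sprintf("no FDR decisions at cutoff %s; run fdr_bh() first.", key))
  }
  n <- sum(map$sig[[key]])
  tibble(n_voxels = as.integer(n),
         volume_ml = n * voxel_volume_ml(map$voxel_dims_mm))
}

#' Run a battery of voxel-wise contrasts
#'
#' Applies [voxelwise_kw()] and [fdr_bh()] at each level of `alphas` to every
#' contrast, and tabulates group sizes, family sizes and suprathreshold
#' counts/volumes in the shape of a per-contrast results table.
#'
#' @param stack a `mask_stack`.
#' @param cohort cohort tibble (used only for labelling; contrasts are built
#'   beforehand with [wmh_contrast()]).
#' @param contrasts list of `wmh_contrast` objects.
#' @param alphas FDR levels, default `c(0.05, 0.01)`.
#' @param min_overlap overlap floor passed to [voxelwise_kw()].
#' @return A `wmh_battery` list: `results` tibble with columns (contrast,
#'   n_target, n_comparison, m_tested, and per alpha `n_sig_*` / `ml_*`), and
#'   `maps`, the fitted `voxel_stat_map` objects.
#' @export
run_contrast_battery <- function(stack, cohort, contrasts,
                                 alphas = c(0.05, 0.01), min_overlap = 2L) {
  stopifnot(length(contrasts) >= 1L)
  maps <- vector("list", length(contrasts))
  rows <- vector("list", length(contrasts))
  for (i in seq_along(contrasts)) {
    map <- voxelwise_kw(stack, contrasts[[i]], min_overlap = min_overlap)
    for (al in alphas) map <- fdr_bh(map, al)
    maps[[i]] <- map
    row <- tibble(contrast = map$label, n_target = map$n_target,
                  n_comparison = map$n_comparison, m_tested = map$m)
    for (al in alphas) {
      cs <- count_significant(map, al)
      row[[paste0("n_sig_", sub("^0\\.", "", alpha_key(al)))]] <- cs$n_voxels
      row[[paste0("ml_", sub("^0\\.", "", alpha_key(al)))]] <- cs$volume_ml
    }
    rows[[i]] <- row
  }
  structure(list(results = dplyr::bind_rows(rows), maps = maps),
            class = "wmh_battery")
}

#' @export
print.wmh_battery <- function(x, ...) {
  cat("<wmh_battery>\n")
  print(as.data.frame(x$results), row.names = FALSE)
  invisible(x)
}
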
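voxel_volume_ml_pub <- function(co) prod(co$config$voxel_dims_mm) / 1000

test_that("overlap floor excludes untestable voxels from the family", {
  M <- matrix(0L, nrow = 4, ncol = 8)
  M[1, 1:6] <- 1L           # well-covered voxel
  M[2, 1] <- 1L             # single-subject voxel: below floor of 2
  st <- make_stack_from_matrix(M)
  contrast <- list(target_ids = sprintf("s%03d", 1:4),
                   comparison_ids = sprintf("s%03d", 5:8))
  map <- voxelwise_kw(st, contrast, min_overlap = 2)
  expect_equal(map$m, 1L)
  expect_true(map$tested[1, 1, 1])
  expect_false(map$tested[2, 1, 1])
  expect_true(is.na(map$P[2, 1, 1]))  # excluded, not P = 1
})

test_that("equal lesion proportions give H = 0 and P = 1", {
  M <- matrix(0L, nrow = 2, ncol = 20)
  M[1, c(1:3, 11:13)] <- 1L  # 3/10 in each group
  st <- make_stack_from_matrix(M)
  contrast <- list(target_ids = sprintf("s%03d", 1:10),
                   comparison_ids = sprintf("s%03d", 11:20))
  map <- voxelwise_kw(st, contrast)
  expect_equal(map$H[1, 1, 1], 0)
  expect_equal(map$P[1, 1, 1], 1)
})

test_that("voxel-wise H and P match the rank-test oracle including ties", {
  # spot value: 8/10 vs 1/10 lesioned
  M <- matrix(0L, nrow = 1, ncol = 20)
  M[1, c(1:8, 11)] <- 1L
  st <- make_stack_from_matrix(M)
  contrast <- list(target_ids = sprintf("s%03d", 1:10),
                   comparison_ids = sprintf("s%03d", 11:20))
  map <- voxelwise_kw(st, contrast)
  oracle <- kw_oracle(8, 1, 10, 10)
  expect_equal(map$H[1, 1, 1], oracle$H, tolerance = 1e-10)
  expect_equal(map$P[1, 1, 1], oracle$P, tolerance = 1e-10)
  # cross-check against the 2x2 hypergeometric enumeration: under the null,
  # P(more extreme tables) from Fisher should broadly order with the KW P
  ft <- stats::fisher.test(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))
  expect_lt(ft$p.value, 0.05)
  expect_lt(map$P[1, 1, 1], 0.05)
})

test_that("voxel-wise KW is invariant to swapping the group labels", {
  set.seed(40)
  M <- matrix(rbinom(50 * 24, 1, 0.3), nrow = 50, ncol = 24)
  st <- make_stack_from_matrix(M, grid = c(50L, 1L, 1L))
  ids <- st$subject_ids
  c1 <- list(target_ids = ids[1:10], comparison_ids = ids[11:24])
  c2 <- list(target_ids = ids[11:24], comparison_ids = ids[1:10])
  m1 <- voxelwise_kw(st, c1)
  m2 <- voxelwise_kw(st, c2)
  expect_equal(m1$H, m2$H, tolerance = 1e-12)
  expect_equal(m1$P, m2$P, tolerance = 1e-12)
})

test_that("BH step-up matches hand execution and is monotone in alpha", {
  # hand case: P = {0.001, 0.02, 0.9} at alpha 0.05 rejects the first two
  M <- matrix(0L, nrow = 3, ncol = 30)
  st <- make_stack_from_matrix(M)
  map <- list(
    P = array(c(0.001, 0.02, 0.9), c(3, 1, 1)),
    H = array(1, c(3, 1, 1)),
    tested = array(TRUE, c(3, 1, 1)), m = 3L,
    n_target = 1L, n_comparison = 1L, voxel_dims_mm = c(1, 1, 1),
    sig = list(), fdr_info = tibble::tibble(alpha = numeric(), m = integer(),
                                            n_rejected = integer(),
                                            p_cutoff = numeric()),
    label = "hand"
  )
  class(map) <- "voxel_stat_map"
  out <- fdr_bh(map, 0.05)
  expect_equal(as.vector(out$sig[["0.05"]]), c(TRUE, TRUE, FALSE))
  expect_equal(out$fdr_info$n_rejected, 2L)
  expect_equal(out$fdr_info$p_cutoff, 0.02)
  # all P = 0.5 with a large family: nothing rejected
  mapb <- map
  mapb$P <- array(0.5, c(3, 1, 1))
  expect_equal(sum(fdr_bh(mapb, 0.05)$sig[["0.05"]]), 0)
  # nestedness of decisions at 0.01 within 0.05
  out <- fdr_bh(out, 0.01)
  expect_true(all(out$sig[["0.01"]] <= out$sig[["0.05"]]))
})

test_that("significant voxel counts convert to millilitres by voxel volume", {
  d <- c(20L, 20L, 20L)
  map <- structure(list(
    P = array(NA_real_, d), H = array(NA_real_, d),
    tested = array(TRUE, d), m = prod(d),
    n_target = 1L, n_comparison = 1L, voxel_dims_mm = c(1, 1, 1),
    sig = list("0.05" = array(c(rep(TRUE, 5530), rep(FALSE, prod(d) - 5530)), d)),
    fdr_info = tibble::tibble(), label = "x"
  ), class = "voxel_stat_map")
  cs <- count_significant(map, 0.05)
  expect_equal(cs$n_voxels, 5530L)
  expect_equal(cs$volume_ml, 5.53)
  expect_error(count_significant(map, 0.01), "run fdr_bh")
})

test_that("a contrast battery reports nested counts and group sizes", {
  co <- generate_cohort(tiny_config(n = 50L, seed = 61L, followup_rate = 0))
  st <- build_mask4d(co$masks$wmh_baseline, names(co$masks$wmh_baseline))
  cs <- wmh_contrast(co$cohort, "rssi", "centrum semiovale")
  bat <- run_contrast_battery(st, co$cohort, list(cs))
  res <- bat$results
  expect_equal(res$n_target, length(cs$target_ids))
  expect_lte(res$n_sig_01, res$n_sig_05)
  expect_equal(res$ml_05, res$n_sig_05 * voxel_volume_ml_pub(co),
               tolerance = 1e-12)
})

test_that("contrast construction follows the location/risk-factor rules", {
  co <- generate_cohort(tiny_config(n = 80L, seed = 62L))
  ct <- co$cohort
  cs <- wmh_contrast(ct, "rssi", "centrum semiovale", risk_factor = "smoking")
  locs <- parse_locations(ct$rssi_locations)
  in_cso <- vapply(locs, function(l) any(l$region == "centrum semiovale"), logical(1))
  has_rssi <- vapply(locs, nrow, integer(1)) > 0
  smoker <- ct$smoking %in% c("current", "recent")
  expect_setequal(cs$target_ids, ct$subject_id[in_cso & smoker])
  expect_setequal(cs$comparison_ids, ct$subject_id[has_rssi & !in_cso & !smoker])
  expect_length(intersect(cs$target_ids, cs$comparison_ids), 0L)
})
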
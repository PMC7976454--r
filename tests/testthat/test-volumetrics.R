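test_that("volume arithmetic follows count x voxel volume / 1000", {
  m <- lesion_mask(array(1L, c(10, 10, 1)), voxel_dims_mm = c(2, 2, 2))
  expect_equal(mask_volume_ml(m), 0.8)  # 100 voxels x 8 mm^3
  expect_equal(mask_volume_ml(lesion_mask(array(0L, c(4, 4, 4)))), 0)
  expect_equal(pct_icv(0, 1469.2), 0)
  expect_equal(pct_icv(14.692, 1469.2), 1.0)
  expect_error(pct_icv(1, 0), "> 0")
  expect_error(pct_icv(-1, 100), ">= 0")
})

test_that("evolution coding is exhaustive and identity-stable", {
  set.seed(2)
  b <- rand_mask(c(8L, 8L, 8L), 0.3)
  same <- evolution_mask(b, b)
  expect_true(all(same$codes %in% c(0L, 2L)))
  expect_equal(evolution_volumes(same)$volume_ml[c(2, 4)], c(0, 0))

  d <- c(6L, 6L, 6L)
  m1 <- array(0L, d); m1[1, 1, 1] <- 1L
  m2 <- array(0L, d); m2[2, 2, 2] <- 1L
  evo <- evolution_mask(lesion_mask(m1), lesion_mask(m2))
  expect_equal(evo$codes[1, 1, 1], 1L)  # regressed
  expect_equal(evo$codes[2, 2, 2], 3L)  # progressed
  expect_error(evolution_mask(b, rand_mask(c(8L, 8L, 6L), 0.3)), "congruent")
})

test_that("evolution conservation identities hold exactly on random pairs", {
  set.seed(17)
  for (rep in 1:25) {
    b <- rand_mask(c(16L, 16L, 16L), runif(1, 0.05, 0.5), voxel = c(1.1, 1.2, 0.9))
    f <- rand_mask(c(16L, 16L, 16L), runif(1, 0.05, 0.5), voxel = c(1.1, 1.2, 0.9))
    evo <- evolution_mask(b, f)
    ev <- evolution_volumes(evo)
    nv <- function(fate) ev$n_voxels[ev$fate == fate]
    vol <- function(fate) ev$volume_ml[ev$fate == fate]
    # conservation is exact in voxel counts ...
    expect_identical(nv("stable") + nv("progressed"), sum(f$values))
    expect_identical(nv("stable") + nv("regressed"), sum(b$values))
    # ... and in ml up to one float rounding of the count x voxel-volume product
    expect_equal(vol("stable") + vol("progressed"), mask_volume_ml(f),
                 tolerance = 1e-12)
    expect_equal(vol("stable") + vol("regressed"), mask_volume_ml(b),
                 tolerance = 1e-12)
    # decode consistency
    expect_identical(evolution_submask(evo, c(2, 3))$values, f$values)
    expect_identical(evolution_submask(evo, c(1, 2))$values, b$values)
    # change from codes equals follow-up minus baseline volume
    expect_equal(vol("progressed") - vol("regressed"),
                 mask_volume_ml(f) - mask_volume_ml(b))
  }
})

test_that("change volumes are signed follow-up minus baseline", {
  co <- generate_cohort(tiny_config(n = 10L, seed = 14L))
  vr <- volume_records(co$cohort)
  id <- co$cohort$subject_id[co$cohort$has_followup][1]
  base <- vr[vr$subject_id == id & vr$timepoint == "baseline", ]
  y1 <- vr[vr$subject_id == id & vr$timepoint == "year1", ]
  ch <- change_volume(base, y1)
  expect_equal(ch$wmh_change_ml, y1$wmh_total_ml - base$wmh_total_ml)
  expect_equal(change_volume(base, base)$wmh_change_ml, 0)
  # direction: a shrinking WMH load yields a negative change
  base2 <- base; y12 <- y1
  base2$wmh_total_ml <- 27.41; y12$wmh_total_ml <- 18.0
  expect_lt(change_volume(base2, y12)$wmh_change_ml, 0)
  base2$wmh_total_ml <- 18.0; y12$wmh_total_ml <- 27.41
  expect_equal(change_volume(base2, y12)$wmh_change_ml, 9.41)
  other <- y1; other$subject_id <- "someone else"
  expect_error(change_volume(base, other), "different subjects")
})

test_that("location summaries use the linear-interpolation quantile rule", {
  co <- generate_cohort(tiny_config(n = 40L, seed = 19L))
  s <- summarize_by_location(co$cohort, "rssi")
  expect_true(all(c("median", "q1", "q3", "descriptive_only") %in% names(s$summary)))
  # counts agree with the generator's draws
  drawn <- table(unlist(lapply(parse_locations(co$cohort$rssi_locations),
                               function(l) paste(l$region, l$hemisphere))))
  got <- setNames(s$counts$n_features, paste(s$counts$region, s$counts$hemisphere))
  expect_equal(got[names(drawn)], setNames(as.integer(drawn), names(drawn)))
  # hand check of the declared quantile convention on {1,2,3,4}
  expect_equal(unname(quantile(1:4, c(0.25, 0.5, 0.75), type = 7)),
               c(1.75, 2.5, 3.25))
  # single-subject group: median = value, q1 = q3 = value
  one <- co$cohort[1, ]
  one$rssi_locations <- "cerebellum,left"
  one$rssi_volume_ml <- 0.5
  s1 <- summarize_by_location(dplyr::bind_rows(
    one, dplyr::mutate(co$cohort[2, ], rssi_locations = "", rssi_volume_ml = 0)
  ), "rssi")
  row <- s1$summary[s1$summary$region == "cerebellum" &
                      s1$summary$measure == "wmh_total_ml" &
                      s1$summary$timepoint == "baseline", ]
  expect_equal(row$median, one$wmh_total_ml)
  expect_equal(row$q1, row$q3)
  expect_true(row$descriptive_only)
})

test_that("tier additivity is preserved through volume records", {
  co <- generate_cohort(tiny_config(n = 15L, seed = 23L))
  vr <- volume_records(co$cohort)
  expect_equal(vr$wmh_intense_ml + vr$wmh_less_intense_ml, vr$wmh_total_ml,
               tolerance = 1e-9)
  expect_equal(vr$wmh_total_pct, 100 * vr$wmh_total_ml / vr$icv_ml,
               tolerance = 1e-12)
})
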
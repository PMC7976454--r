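make_features <- function(n = 30L, grid = c(8L, 8L, 8L), seed = 1L,
                          p_mask = 0.4) {
  set.seed(seed)
  mask <- array(runif(prod(grid)) < p_mask, grid)
  evo <- lapply(seq_len(n), function(i) {
    b <- rand_mask(grid, 0.25)
    f <- rand_mask(grid, 0.25)
    evolution_mask(b, f)
  })
  names(evo) <- sprintf("s%03d", seq_len(n))
  list(feats = build_change_features(evo, mask), evo = evo, mask = mask)
}

test_that("change features encode progression/regression and audit volumetrics", {
  mf <- make_features(n = 15L, seed = 3L)
  feats <- mf$feats
  expect_s4_class(feats$X, "dgCMatrix")
  expect_equal(nrow(feats$X), 15L)
  expect_equal(ncol(feats$X), sum(mf$mask))
  expect_false(anyDuplicated(feats$voxel_linear) > 0)
  # column sums equal per-voxel (progressed - regressed) counts
  prog <- Reduce(`+`, lapply(mf$evo, function(e) (e$codes == 3L)[mf$mask]))
  regr <- Reduce(`+`, lapply(mf$evo, function(e) (e$codes == 1L)[mf$mask]))
  expect_equal(unname(Matrix::colSums(feats$X)), as.numeric(prog - regr))
  # a subject with no change contributes an all-zero row
  same <- rand_mask(c(8L, 8L, 8L), 0.3)
  evo0 <- list(s1 = evolution_mask(same, same))
  f0 <- build_change_features(evo0, mf$mask)
  expect_equal(Matrix::nnzero(f0$X), 0)
})

test_that("SGD runs are seed-deterministic and lambda shrinks weights", {
  mf <- make_features(n = 25L, seed = 5L)
  y <- rnorm(25)
  a1 <- fit_sgd_ridge(mf$feats, y, epochs = 10, seed = 9)
  a2 <- fit_sgd_ridge(mf$feats, y, epochs = 10, seed = 9)
  expect_identical(a1$weights, a2$weights)
  # ridge-limit: enormous penalty kills all voxel weights
  big <- fit_sgd_ridge(mf$feats, y, lambda = 1e9, epochs = 10, seed = 9)
  expect_lt(max(abs(big$weights)), 1e-6)
  # monotone shrinkage of the weight norm in lambda
  norms <- vapply(c(0.01, 0.1, 1, 10), function(l) {
    sqrt(sum(fit_sgd_ridge(mf$feats, y, lambda = l, epochs = 20,
                           seed = 9, loss = "squared")$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("squared-loss SGD matches the closed-form ridge oracle", {
  set.seed(123)
  grid <- c(15L, 1L, 1L)
  mask <- array(TRUE, grid)
  for (s in 1:3) {
    n <- 40L
    X <- matrix(rnorm(n * 15), n, 15)
    pres <- lapply(seq_len(n), function(i) {
      lesion_mask(array(as.integer(X[i, ] > 0), grid))
    })
    names(pres) <- sprintf("s%03d", seq_len(n))
    feats <- build_change_features(pres, mask)  # presence mode: X is 0/1
    Xb <- as.matrix(feats$X)
    beta <- rnorm(15)
    y <- drop(Xb %*% beta) + rnorm(n, sd = 0.3)
    fit <- fit_sgd_ridge(feats, y, lambda = 1 / 47, epochs = 3000, seed = s,
                         loss = "squared", intercept = FALSE)
    oracle <- drop(ridge_oracle(Xb, y, 1 / 47))
    relerr <- sqrt(sum((fit$weights - oracle)^2)) / sqrt(sum(oracle^2))
    expect_lt(relerr, 1e-3)
  }
})

test_that("sign-split maps reconstruct the weights exactly", {
  mf <- make_features(n = 20L, seed = 8L)
  fit <- fit_sgd_ridge(mf$feats, rnorm(20), epochs = 15, seed = 2)
  w_back <- (fit$positive - fit$negative)[mf$feats$voxel_linear]
  expect_identical(w_back, fit$weights)
  expect_true(all(fit$positive >= 0) && all(fit$negative >= 0))
})

test_that("response encoding round-trips the proforma codes", {
  tab <- location_code_table()
  expect_equal(nrow(tab), 14L)
  # bijection audit: every region x hemisphere code decodes to itself
  for (i in seq_len(nrow(tab))) {
    dec <- wmhevolve:::code_to_location(tab$code[i])
    expect_equal(dec$region, tab$region[i])
    expect_equal(dec$hemisphere, tab$hemisphere[i])
  }
  co <- generate_cohort(tiny_config(n = 40L, seed = 13L))
  y <- encode_response(co$cohort, "location_code")
  locs <- parse_locations(co$cohort$rssi_locations)
  expect_true(all(y[vapply(locs, nrow, integer(1)) == 0] == 0))
  # indicator mode matches the table
  yi <- encode_response(co$cohort, "location_indicator", region = "centrum semiovale")
  manual <- vapply(locs, function(l) {
    as.numeric(nrow(l) > 0 && l$region[[1]] == "centrum semiovale")
  }, numeric(1))
  expect_equal(yi, manual)
  # constant response is flagged degenerate
  ct <- co$cohort
  ct$rssi_locations <- ""
  ct$rssi_volume_ml <- 0
  expect_warning(y0 <- encode_response(ct, "location_code"), "degenerate")
  expect_true(attr(y0, "degenerate"))
})

test_that("display rescaling saturates at the chosen fraction of the maximum", {
  mf <- make_features(n = 20L, seed = 10L)
  fit <- fit_sgd_ridge(mf$feats, rnorm(20), epochs = 15, seed = 4)
  disp <- rescale_for_display(fit, 0.5)
  expect_true(all(disp$positive >= 0 & disp$positive <= 1))
  # voxels at >= 50% of max in the raw map are exactly the saturated ones
  thr <- 0.5 * max(fit$positive)
  expect_equal(sum(disp$positive >= 1), sum(fit$positive >= thr))
  # all-zero side flagged
  fit0 <- fit
  fit0$negative <- array(0, fit$grid_dims)
  d0 <- rescale_for_display(fit0, 0.5)
  expect_true(d0$negative_empty)
  expect_true(all(d0$negative == 0))
  expect_error(rescale_for_display(fit, 0), "fraction")
})

test_that("planted progression linked to RSSI location yields positive weights", {
  # subjects with capsule RSSI get planted progression in a fixed region
  set.seed(99)
  grid <- c(10L, 10L, 10L)
  region_lin <- which(array(seq_len(1000), grid) <= 200)  # fixed 200-voxel block
  n <- 40L
  hits <- 0L
  for (s in 1:5) {
    set.seed(300 + s)
    capsule <- rbinom(n, 1, 0.5)
    evo <- lapply(seq_len(n), function(i) {
      b <- rand_mask(grid, 0.15)
      f <- b$values
      pr <- if (capsule[i] == 1) 0.5 else 0.05
      f[region_lin] <- ifelse(runif(200) < pr, 1L, f[region_lin])
      evolution_mask(b, lesion_mask(array(f, grid)))
    })
    names(evo) <- sprintf("s%03d", seq_len(n))
    feats <- build_change_features(evo, array(TRUE, grid))
    fit <- fit_sgd_ridge(feats, as.numeric(capsule), epochs = 60, seed = s)
    w_region <- fit$weights[match(region_lin, feats$voxel_linear)]
    if (mean(w_region) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
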
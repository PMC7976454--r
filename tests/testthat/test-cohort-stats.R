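test_that("OLS recovers an exact linear relation with zero residuals", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20))
  fit <- fit_wmh_lm(d, y ~ x)
  td <- suppressWarnings(tidy(fit))  # lm warns on an essentially perfect fit
  expect_equal(td$estimate[td$term == "x"], 2, tolerance = 1e-12)
  expect_equal(unname(stats::residuals(fit$fit)), rep(0, 20), tolerance = 1e-10)
})

test_that("coefficients match a pseudoinverse oracle on random designs", {
  set.seed(55)
  for (rep in 1:8) {
    n <- sample(30:200, 1)
    p <- sample(2:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    d <- as.data.frame(X)
    d$y <- y
    fit <- fit_wmh_lm(d, y ~ .)
    beta_hat <- coef(fit$fit)
    Xi <- cbind(1, X)
    oracle <- drop(solve(crossprod(Xi), crossprod(Xi, y)))
    expect_equal(unname(beta_hat), unname(oracle), tolerance = 1e-8)
  }
})

test_that("rank deficiency and missing data are handled explicitly", {
  d <- tibble::tibble(y = rnorm(30), a = rnorm(30))
  d$b <- d$a  # duplicated predictor
  expect_error(fit_wmh_lm(d, y ~ a + b), "aliased")
  expect_error(fit_wmh_lm(d, y ~ y + a), "response")
  d2 <- tibble::tibble(y = rnorm(30), x = rnorm(30))
  d2$x[1:5] <- NA
  fit <- fit_wmh_lm(d2, y ~ x)
  expect_equal(fit$n_used, 25L)
  expect_equal(fit$n_dropped, 5L)
  expect_equal(glance(fit)$n_used, 25L)
})

test_that("Kruskal-Wallis H and P match stats::kruskal.test with ties", {
  set.seed(66)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    g <- rep(seq_len(k), times = sample(5:15, k, replace = TRUE))
    # heavy ties: integer values
    x <- sample(1:4, length(g), replace = TRUE)
    res <- kruskal_groups(x, g, method = "chisq")
    kt <- suppressWarnings(stats::kruskal.test(x, factor(g)))
    expect_equal(res$statistic, unname(kt$statistic), tolerance = 1e-9)
    expect_equal(res$p.value, kt$p.value, tolerance = 1e-9)
  }
  # identical groups: degenerate, H = 0 and P = 1
  res0 <- kruskal_groups(rep(5, 10), rep(1:2, each = 5))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_error(kruskal_groups(1:5, rep(1, 5)), "2 groups")
})

test_that("Kruskal-Wallis is invariant to strictly monotone transforms", {
  set.seed(77)
  x <- rlnorm(30)
  g <- rep(1:3, each = 10)
  h0 <- kruskal_groups(x, g, method = "chisq")$statistic
  for (f in list(log, sqrt, function(v) v^3, function(v) 5 * v - 2)) {
    expect_equal(kruskal_groups(f(x), g, method = "chisq")$statistic, h0,
                 tolerance = 1e-12)
  }
})

test_that("small-sample permutation path is exact for two groups", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(1:2, each = 3)
  res <- kruskal_groups(x, g)  # auto -> permutation at n <= 12
  expect_equal(res$method, "permutation")
  # enumerate all 20 assignments by hand through the public statistic
  combs <- utils::combn(6, 3)
  stats_all <- apply(combs, 2, function(idx) {
    kruskal_groups(x, ifelse(seq_len(6) %in% idx, "a", "b"),
                   method = "chisq")$statistic
  })
  p_manual <- mean(stats_all >= res$statistic - 1e-12)
  expect_equal(res$p.value, p_manual, tolerance = 1e-12)
})

test_that("ranked Levene test is calibrated under the null and detects spread", {
  set.seed(88)
  p_null <- replicate(200, {
    levene_ranked(rnorm(40), rep(1:2, each = 20))$p.value
  })
  ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 0.01)
  p_alt <- replicate(50, {
    x <- c(rnorm(60), rnorm(60, sd = 10))
    levene_ranked(x, rep(1:2, each = 60))$p.value
  })
  expect_gte(mean(p_alt < 0.05), 0.95)
  expect_error(levene_ranked(c(1, 2, 3), c(1, 1, 2)), "at least 2")
})

test_that("location recoding handles primary and multi-cluster paths", {
  co <- generate_cohort(tiny_config(n = 30L, seed = 31L,
                                    multi_cluster_rate = 0.5))
  single <- recode_locations(co$cohort, "primary_only")
  multi <- recode_locations(co$cohort, "multi_cluster")
  locs <- parse_locations(co$cohort$rssi_locations)
  n_cl <- vapply(locs, function(l) length(unique(l$region)), integer(1))
  expect_identical(single[n_cl <= 1], multi[n_cl <= 1])
  expect_true(all(single[n_cl == 0] == "none"))
  expect_true(all(grepl(" \\+ ", multi[n_cl > 1])))
  # primary = largest cluster, the first listed code
  i <- which(n_cl > 1)[1]
  expect_equal(single[i], locs[[i]]$region[1])
  # composite code is order-independent
  ct <- co$cohort
  ct$rssi_locations[i] <- paste(rev(strsplit(ct$rssi_locations[i], ";")[[1]]),
                                collapse = ";")
  expect_equal(recode_locations(ct, "multi_cluster")[i], multi[i])
  # volume/code inconsistency is an error
  bad <- co$cohort
  bad$wmh_total_ml[1] <- bad$wmh_total_ml[1]  # no-op, keep valid elsewhere
  bad$rssi_volume_ml[1] <- 1
  bad$rssi_locations[1] <- ""
  expect_error(recode_locations(bad, "primary_only"), "inconsistent")
})

test_that("ANCOVA location term is null-calibrated on covariate-free response", {
  set.seed(101)
  pvals <- replicate(60, {
    n <- 80
    d <- tibble::tibble(
      y = rnorm(n),
      age = rnorm(n, 65, 11),
      region = factor(sample(c("capsule", "cso", "thalamus"), n, replace = TRUE))
    )
    td <- tidy(fit_wmh_ancova(d, y ~ region + age))
    min(td$p.value[grepl("region", td$term)])
  })
  # p-values of a null term should not pile up near zero
  expect_gt(mean(pvals > 0.05), 0.80)
})
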
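# shared fixtures and independent oracles

tiny_config <- function(n = 20L, grid = 16L, seed = 1L, ...) {
  generator_config(n_subjects = n, grid_dims = rep(grid, 3L), seed = seed, ...)
}

rand_mask <- function(grid = c(16L, 16L, 16L), p = 0.2, voxel = c(1, 1, 1)) {
  lesion_mask(array(as.integer(runif(prod(grid)) < p), grid), voxel)
}

make_stack_from_matrix <- function(M, grid = NULL) {
  # M: voxels x subjects 0/1
  n <- ncol(M)
  if (is.null(grid)) grid <- c(nrow(M), 1L, 1L)
  masks <- lapply(seq_len(n), function(i) {
    lesion_mask(array(as.integer(M[, i]), grid))
  })
  build_mask4d(masks, sprintf("s%03d", seq_len(n)))
}

# independent oracle: from-scratch rank/tie Kruskal-Wallis on the expanded
# 0/1 observations, computed through explicit ranks rather than counts
kw_oracle <- function(a, b, n1, n2) {
  x <- c(rep(1, a), rep(0, n1 - a), rep(1, b), rep(0, n2 - b))
  g <- rep(c("t", "c"), c(n1, n2))
  if (length(unique(x)) == 1L) return(list(H = 0, P = 1))
  N <- n1 + n2
  r <- rank(x)
  dev <- tapply(r, g, mean) - (N + 1) / 2
  nj <- tapply(r, g, length)
  H_raw <- 12 / (N * (N + 1)) * sum(nj * dev^2)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H_raw / C
  list(H = H, P = stats::pchisq(H, df = 1, lower.tail = FALSE))
}

# independent oracle: closed-form ridge estimator
ridge_oracle <- function(X, y, lambda) {
  n <- nrow(X)
  solve(crossprod(X) + n * lambda * diag(ncol(X)), crossprod(X, y))
}

# independent oracle: flood fill by repeated dilation within the candidate set
flood_oracle <- function(image, seed_voxel, floor) {
  candidate <- image >= floor
  if (!candidate[seed_voxel[1], seed_voxel[2], seed_voxel[3]]) {
    return(array(FALSE, dim(image)))
  }
  cur <- array(FALSE, dim(image))
  cur[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
  repeat {
    nxt <- (wmhevolve:::dilate_box(cur) & candidate) | cur
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# cohorts shared by the slope-recovery checks (computed once per session)
.recovery_cache <- new.env(parent = emptyenv())

recovery_cohorts <- function(n_seeds = 20L, n = 500L) {
  key <- sprintf("s%d_n%d", n_seeds, n)
  if (is.null(.recovery_cache[[key]])) {
    .recovery_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      cfg <- generator_config(n_subjects = n, grid_dims = c(24L, 24L, 24L),
                              seed = 20000L + s)
      generate_cohort(cfg)$cohort
    })
  }
  .recovery_cache[[key]]
}

slope_in_ci <- function(fit, term, truth) {
  # HC3 intervals: the planted links have mean-proportional (Poisson-like)
  # noise, under which classical OLS intervals under-cover
  td <- tidy(fit, conf.int = TRUE, robust = TRUE)
  row <- td[td$term == term, ]
  truth >= row$conf.low && truth <= row$conf.high
}
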
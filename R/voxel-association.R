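#' Build sparse voxel change features from evolution maps
#'
#' Assembles the subject-by-voxel feature matrix of WMH fate used by the
#' voxel association model: inside the analysis mask, entry (subject, voxel)
#' is +1 where WMH progressed, -1 where it regressed and 0 otherwise. In
#' baseline mode (a list of [lesion_mask] objects instead of evolution maps)
#' entries are 0/1 WMH presence. Columns are ordered by voxel linear index,
#' deterministically.
#'
#' @param maps named list of `evolution_map` objects (change mode) or
#'   [lesion_mask] objects (baseline presence mode), one per subject.
#' @param analysis_mask [lesion_mask] or logical 3D array selecting the voxels
#'   that become features.
#' @return A `change_features` list: sparse `X` (subjects x voxels,
#'   `Matrix::dgCMatrix`), `voxel_linear`, `coords` (n x 3), `subject_ids`,
#'   `grid_dims`, `voxel_dims_mm` and `mode`.
#' @export
build_change_features <- function(maps, analysis_mask) {
  if (length(maps) < 1L) abort("need at least one subject map.")
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    abort("`maps` must be a named list (subject ids).")
  }
  mode <- if (inherits(maps[[1]], "evolution_map")) "change" else "presence"
  mask_arr <- if (inherits(analysis_mask, "lesion_mask")) {
    analysis_mask$values > 0
  } else {
    analysis_mask
  }
  gd <- dim(mask_arr)
  if (!any(mask_arr)) abort("empty analysis mask.")
  voxel_linear <- which(mask_arr)
  coords <- arrayInd(voxel_linear, gd)
  p <- length(voxel_linear)
  n <- length(maps)
  vdm <- NULL
  triplets <- vector("list", n)
  for (i in seq_len(n)) {
    m <- maps[[i]]
    if (mode == "change") {
      stopifnot(inherits(m, "evolution_map"))
      vals_full <- m$codes
      if (!identical(dim(vals_full), gd)) abort("map grid differs from analysis mask.")
      v <- vals_full[voxel_linear]
      x <- integer(p)
      x[v == 3L] <- 1L
      x[v == 1L] <- -1L
    } else {
      stopifnot(inherits(m, "lesion_mask"))
      if (!identical(dim(m$values), gd)) abort("map grid differs from analysis mask.")
      x <- as.integer(m$values[voxel_linear] > 0)
    }
    vdm_i <- m$voxel_dims_mm
    if (is.null(vdm)) vdm <- vdm_i
    if (any(abs(vdm - vdm_i) > 1e-6)) abort("voxel dimensions differ across maps.")
    nz <- which(x != 0L)
    triplets[[i]] <- list(j = nz, x = x[nz])
  }
  ii <- rep(seq_len(n), vapply(triplets, function(t) length(t$j), integer(1)))
  jj <- unlist(lapply(triplets, `[[`, "j"))
  xx <- unlist(lapply(triplets, `[[`, "x"))
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                            dims = c(n, p))
  structure(
    list(X = X, voxel_linear = voxel_linear, coords = coords,
         subject_ids = names(maps), grid_dims = gd,
         voxel_dims_mm = vdm, mode = mode),
    class = "change_features"
  )
}

#' @export
print.change_features <- function(x, ...) {
  cat(sprintf("<change_features> %d subjects x %d voxels (%s mode), %d non-zeros\n",
              nrow(x$X), ncol(x$X), x$mode, Matrix::nnzero(x$X)))
  invisible(x)
}

#' Encode the RSSI location response for the association model
#'
#' `location_code` emits the proforma's integer code of the primary (largest)
#' RSSI cluster (see [location_code_table()]; 0 for subjects without an RSSI).
#' `location_indicator` emits 1 for subjects whose primary cluster lies in the
#' named region and 0 otherwise. A constant result is flagged with a warning
#' (attribute `degenerate`), since a constant response carries no signal.
#'
#' @param cohort cohort tibble.
#' @param mode `"location_code"` or `"location_indicator"`.
#' @param region region name, required in indicator mode.
#' @return Numeric vector aligned with cohort rows.
#' @export
encode_response <- function(cohort, mode = c("location_code", "location_indicator"),
                            region = NULL) {
  mode <- match.arg(mode)
  cohort <- validate_cohort(cohort)
  locs <- parse_locations(cohort$rssi_locations)
  out <- if (mode == "location_code") {
    vapply(locs, function(l) {
      if (nrow(l) == 0) 0 else as.numeric(location_to_code(l$region[[1]], l$hemisphere[[1]]))
    }, numeric(1))
  } else {
    if (is.null(region)) abort("`region` is required in indicator mode.")
    if (!region %in% wmh_regions()) abort(sprintf("unknown region: %s", region))
    vapply(locs, function(l) {
      as.numeric(nrow(l) > 0 && l$region[[1]] == region)
    }, numeric(1))
  }
  if (length(unique(out)) == 1L) {
    warn("encoded response is constant; flagged degenerate.")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Ridge-penalised SVM-style regression over voxel features by SGD
#'
#' Fits a linear model of an encoded subject-level response on high-dimensional
#' sparse voxel features, minimising mean epsilon-insensitive loss plus a
#' ridge penalty `lambda * ||w||^2 / 2` on the voxel weights; the intercept
#' and covariate coefficients (e.g. age) are unpenalised. Optimisation is
#' stochastic gradient descent with the decaying step schedule
#' `eta_t = eta0 / (1 + decay * t)`, per-epoch shuffling fixed by `seed`, and
#' Polyak-Ruppert averaging of the iterates over the second half of training.
#' Runs are fully deterministic given the seed.
#'
#' The default loss is epsilon-insensitive (support-vector regression), with
#' `epsilon` defaulting to `IQR(response) / 13.49`, the dispersion-based
#' convention of common SVR implementations. A squared-loss mode exists so the
#' optimiser can be validated against the closed-form ridge estimator
#' `(X'X + n lambda I)^-1 X'y`; with `loss = "squared"`, `epsilon = 0`, no
#' intercept and no covariates the SGD solution matches that estimator.
#'
#' @param features a `change_features` from [build_change_features()].
#' @param response numeric vector, one value per subject (see
#'   [encode_response()]).
#' @param covariates optional numeric matrix / data frame of unpenalised
#'   covariates (standardised internally; coefficients reported on the
#'   original scale).
#' @param lambda ridge strength (>= 0); the default 1/47 follows the reference
#'   analysis this model reproduces. With `lambda_times_n = TRUE` the penalty
#'   is multiplied by the sample size (the alternative normalisation
#'   convention).
#' @param epsilon insensitivity half-width; `NULL` for the IQR-based default.
#' @param epochs full passes over the data (>= 1).
#' @param seed integer seed controlling shuffling.
#' @param loss `"epsilon_insensitive"` or `"squared"`.
#' @param eta0,decay step-size schedule parameters; `decay` defaults to
#'   `eta0 * max(lambda, 1e-3)`.
#' @param intercept include an unpenalised intercept (default TRUE).
#' @param average Polyak-Ruppert averaging over the second half of training.
#' @param lambda_times_n use `lambda * n` as the effective penalty.
#' @return An `association_map`: per-voxel `weights`, sign-split 3D
#'   `positive` / `negative` fields, `intercept`, `covariate_coefs`,
#'   hyperparameters, and a per-epoch objective log.
#' @export
fit_sgd_ridge <- function(features, response, covariates = NULL,
                          lambda = 1 / 47, epsilon = NULL, epochs = 50L,
                          seed = 1L, loss = c("epsilon_insensitive", "squared"),
                          eta0 = 0.05, decay = NULL, intercept = TRUE,
                          average = TRUE, lambda_times_n = FALSE) {
  loss <- match.arg(loss)
  stopifnot(inherits(features, "change_features"))
  X <- as.matrix(features$X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(response) != n) abort("response length must equal the number of subjects.")
  if (any(!is.finite(response))) abort("non-finite response.")
  if (lambda < 0) abort("`lambda` must be >= 0.")
  if (epochs < 1L) abort("`epochs` must be >= 1.")
  lam <- if (lambda_times_n) lambda * n else lambda
  if (is.null(epsilon)) {
    epsilon <- if (loss == "squared") 0 else unname(diff(quantile(response, c(0.25, 0.75)))) / 13.49
  }
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  decay <- decay %||% (eta0 * max(lam, 1e-3))

  Z <- NULL
  z_centre <- z_scale <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) abort("covariate rows must match subjects.")
    z_centre <- colMeans(Z)
    z_scale <- apply(Z, 2, sd)
    z_scale[z_scale == 0] <- 1
    Z <- sweep(sweep(Z, 2, z_centre), 2, z_scale, "/")
  }
  q <- if (is.null(Z)) 0L else ncol(Z)

  w <- numeric(p)
  g <- numeric(q)          # covariate coefficients on the standardised scale
  b <- if (intercept) mean(response) else 0
  wbar <- numeric(p); gbar <- numeric(q); bbar <- 0; navg <- 0L
  burn <- floor(epochs / 2)
  t <- 0
  loss_log <- numeric(epochs)

  objective <- function(w, g, b) {
    f <- drop(X %*% w) + b + (if (q) drop(Z %*% g) else 0)
    r <- response - f
    l <- if (loss == "squared") 0.5 * r^2 else pmax(abs(r) - epsilon, 0)
    mean(l) + lam / 2 * sum(w^2)
  }

  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      t <- t + 1
      eta <- eta0 / (1 + decay * t)
      f_i <- sum(X[i, ] * w) + b + (if (q) sum(Z[i, ] * g) else 0)
      r <- response[i] - f_i
      grad_f <- if (loss == "squared") -r else if (abs(r) > epsilon) -sign(r) else 0
      w <- (1 - eta * lam) * w
      if (grad_f != 0) {
        w <- w - eta * grad_f * X[i, ]
        if (q) g <- g - eta * grad_f * Z[i, ]
        if (intercept) b <- b - eta * grad_f
      }
      if (average && ep > burn) {
        navg <- navg + 1L
        wbar <- wbar + (w - wbar) / navg
        if (q) gbar <- gbar + (g - gbar) / navg
        bbar <- bbar + (b - bbar) / navg
      }
    }
    loss_log[ep] <- objective(w, g, b)
  }
  if (average && navg > 0L) {
    w <- wbar
    if (q) g <- gbar
    b <- bbar
  }

  covariate_coefs <- NULL
  if (q) {
    covariate_coefs <- g / z_scale
    names(covariate_coefs) <- colnames(Z) %||% paste0("z", seq_len(q))
    b <- b - sum(covariate_coefs * z_centre)
  }

  gd <- features$grid_dims
  positive <- negative <- array(0, gd)
  positive[features$voxel_linear] <- pmax(w, 0)
  negative[features$voxel_linear] <- pmax(-w, 0)

  structure(
    list(
      weights = w, intercept = if (intercept) b else 0,
      covariate_coefs = covariate_coefs,
      positive = positive, negative = negative,
      voxel_linear = features$voxel_linear, grid_dims = gd,
      voxel_dims_mm = features$voxel_dims_mm,
      hyper = list(lambda = lambda, lambda_effective = lam, epsilon = epsilon,
                   epochs = epochs, seed = seed, loss = loss, eta0 = eta0,
                   decay = decay, average = average,
                   lambda_times_n = lambda_times_n),
      loss_log = tibble(epoch = seq_len(epochs), objective = loss_log)
    ),
    class = "association_map"
  )
}

#' @export
print.association_map <- function(x, ...) {
  cat(sprintf(
    "<association_map> %d voxel weights (|w| max %.4g), lambda = %.4g, loss = %s\n",
    length(x$weights), max(abs(x$weights)), x$hyper$lambda, x$hyper$loss
  ))
  invisible(x)
}

#' Rescale association maps for display
#'
#' Divides the positive and the negative map each by `fraction` times its own
#' maximum and clips to \[0, 1\], so values at or above that fraction of the
#' maximum saturate. Purely a visualisation aid; never feed the rescaled maps
#' back into statistics. An all-zero map comes back as zeros with a flag.
#'
#' @param map an `association_map`.
#' @param fraction saturation point as a fraction of each map's maximum,
#'   in (0, 1\].
#' @return List with `positive` and `negative` display arrays in \[0, 1\] and
#'   logical flags `positive_empty` / `negative_empty`.
#' @export
rescale_for_display <- function(map, fraction = 0.5) {
  stopifnot(inherits(map, "association_map"))
  if (!(fraction > 0 && fraction <= 1)) abort("`fraction` must lie in (0, 1].")
  scale_one <- function(a) {
    m <- max(a)
    if (m <= 0) return(list(map = a, empty = TRUE))
    out <- a / (fraction * m)
    out[out > 1] <- 1
    list(map = out, empty = FALSE)
  }
  pos <- scale_one(map$positive)
  neg <- scale_one(map$negative)
  list(positive = pos$map, negative = neg$map,
       positive_empty = pos$empty, negative_empty = neg$empty)
}
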
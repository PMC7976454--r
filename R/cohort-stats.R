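#' Linear regression of WMH volume on lesion measures
#'
#' Ordinary least-squares fit with listwise deletion of incomplete rows and an
#' explicit full-rank requirement: aliased terms are an error naming the
#' offending columns rather than silently dropped coefficients. Categorical
#' predictors expand to indicator contrasts against their reference level
#' (first level, or set `relevel` beforehand). Two-sided t-based p-values are
#' reported per coefficient.
#'
#' `fit_wmh_ancova()` is the same machinery used with a continuous response
#' (e.g. one-year WMH change) and a mix of categorical and continuous
#' covariates, which is how the covariance analysis is realised.
#'
#' @param data data frame (typically a cohort tibble, possibly augmented with
#'   derived columns such as WMH change).
#' @param formula model formula; the response must not reappear on the
#'   right-hand side.
#' @return A `wmh_fit` object; use [tidy()] for the per-term table (term, B,
#'   SE, P) and [glance()] for model-level summaries.
#' @export
fit_wmh_lm <- function(data, formula) {
  tf <- stats::terms(formula, data = data)
  formula <- stats::formula(tf)  # expands a "." right-hand side
  vars <- all.vars(attr(tf, "variables"))
  response <- vars[attr(tf, "response")]
  if (response %in% all.vars(formula[[3]])) {
    abort("response must not appear among the predictors.")
  }
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(sprintf("variable(s) not in data: %s", paste(missing_vars, collapse = ", ")))
  }
  used <- data[, vars, drop = FALSE]
  keep <- complete.cases(used)
  n_used <- sum(keep)
  n_dropped <- sum(!keep)
  mm <- model.matrix(formula, data = used[keep, , drop = FALSE])
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    fit0 <- lm(formula, data = used[keep, , drop = FALSE])
    aliased <- names(coef(fit0))[is.na(coef(fit0))]
    abort(sprintf("rank-deficient design; aliased term(s): %s",
                  paste(aliased, collapse = ", ")))
  }
  if (n_used <= ncol(mm)) abort("zero residual degrees of freedom.")
  fit <- lm(formula, data = used[keep, , drop = FALSE])
  structure(
    list(fit = fit, formula = formula, n_used = n_used, n_dropped = n_dropped),
    class = "wmh_fit"
  )
}

#' @rdname fit_wmh_lm
#' @export
fit_wmh_ancova <- fit_wmh_lm

#' @export
print.wmh_fit <- function(x, ...) {
  cat(sprintf("<wmh_fit> %s  (n used = %d, dropped = %d)\n",
              deparse(x$formula), x$n_used, x$n_dropped))
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_wmh_lm
#' @param x a `wmh_fit`.
#' @param conf.int,conf.level add a confidence interval per term.
#' @param robust use heteroscedasticity-consistent (HC3 sandwich) standard
#'   errors for the interval and `std.error` column. Appropriate when the
#'   response noise scales with its mean, as count-like volumes do; point
#'   estimates and the classical t-based `p.value` are unchanged.
#' @param ... unused.
#' @export
tidy.wmh_fit <- function(x, conf.int = FALSE, conf.level = 0.95,
                         robust = FALSE, ...) {
  s <- summary(x$fit)$coefficients
  se <- if (robust) {
    sqrt(diag(sandwich::vcovHC(x$fit, type = "HC3")))
  } else {
    s[, 2]
  }
  out <- tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(se),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
  if (conf.int) {
    tq <- qt(1 - (1 - conf.level) / 2, df = x$fit$df.residual)
    out$conf.low <- out$estimate - tq * out$std.error
    out$conf.high <- out$estimate + tq * out$std.error
  }
  out
}

#' @export
glance.wmh_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, df.residual = x$fit$df.residual,
    n_used = x$n_used, n_dropped = x$n_dropped
  )
}

# tie-corrected Kruskal-Wallis H from ranks; shared by the subject-level test
# and (in closed form over counts) the voxel-wise machinery
kw_h_statistic <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  dev <- Rj / nj - (N + 1) / 2  # deviation form avoids large-term cancellation
  H_raw <- 12 / (N * (N + 1)) * sum(nj * dev^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) 0 else H_raw / C
}

#' Kruskal-Wallis test with tie correction and a small-sample exact option
#'
#' Computes the tie-corrected H statistic from ranks. P-values come from the
#' chi-squared approximation with k-1 degrees of freedom, or from the
#' permutation distribution: exact enumeration over group assignments for two
#' groups, Monte-Carlo permutation otherwise. With `method = "auto"` the
#' permutation path is taken for total n <= 12, where the chi-squared
#' approximation is poorest. If every observation is identical, H is defined
#' as 0 with P = 1 (returned, not an error).
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups, each with >= 1 observation).
#' @param method `"auto"`, `"chisq"` or `"permutation"`.
#' @param n_perm Monte-Carlo permutation count for k > 2 groups.
#' @return Tibble with `statistic`, `df`, `p.value`, `method`, `n`.
#' @export
kruskal_groups <- function(values, groups,
                           method = c("auto", "chisq", "permutation"),
                           n_perm = 9999L) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (length(values) != length(groups)) abort("length mismatch.")
  if (anyNA(values) || anyNA(groups)) abort("missing values are not allowed.")
  k <- nlevels(droplevels(groups))
  groups <- droplevels(groups)
  if (k < 2L) abort("need at least 2 groups.")
  N <- length(values)
  H <- kw_h_statistic(values, groups)
  if (method == "auto") method <- if (N <= 12L) "permutation" else "chisq"
  if (H == 0 && length(unique(values)) == 1L) {
    return(tibble(statistic = 0, df = k - 1L, p.value = 1,
                  method = "degenerate", n = N))
  }
  if (method == "chisq") {
    p <- pchisq(H, df = k - 1L, lower.tail = FALSE)
  } else if (k == 2L) {
    # exact: enumerate assignments of observations to group 1
    n1 <- sum(groups == levels(groups)[1])
    combs <- utils::combn(N, n1)
    stats <- apply(combs, 2, function(idx) {
      g <- factor(ifelse(seq_len(N) %in% idx, "a", "b"))
      kw_h_statistic(values, g)
    })
    p <- mean(stats >= H - 1e-12)
  } else {
    stats <- vapply(seq_len(n_perm), function(i) {
      kw_h_statistic(values, sample(groups))
    }, numeric(1))
    p <- (1 + sum(stats >= H - 1e-12)) / (n_perm + 1)
  }
  tibble(statistic = H, df = k - 1L, p.value = p, method = method, n = N)
}

#' Rank-based (non-parametric) Levene test for homogeneity of variance
#'
#' Levene's procedure applied to ranked data: observations are replaced by
#' their ranks, absolute deviations from each group's median rank are formed,
#' and a one-way ANOVA F test is run on those deviations.
#'
#' @param values numeric observations.
#' @param groups group labels; every group needs n >= 2.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p.value`, `n`.
#' @export
levene_ranked <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (length(values) != length(groups)) abort("length mismatch.")
  if (nlevels(groups) < 2L) abort("need at least 2 groups.")
  nj <- tabulate(groups)
  if (any(nj < 2L)) abort("every group needs at least 2 observations.")
  r <- rank(values)
  med <- tapply(r, groups, median)
  d <- abs(r - med[as.integer(groups)])
  fit <- stats::oneway.test(d ~ groups, var.equal = TRUE)
  tibble(statistic = unname(fit$statistic),
         df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
         p.value = fit$p.value, n = length(values))
}

#' Recode RSSI locations for the dual analysis path
#'
#' All location-based models can be run twice: once using only the primary
#' (largest) RSSI cluster's code, and once with a composite code that keeps
#' every cluster for multi-cluster subjects. Subjects without an RSSI receive
#' `"none"` and are excluded from RSSI-location models downstream.
#'
#' @param cohort cohort tibble.
#' @param mode `"primary_only"` or `"multi_cluster"`.
#' @param by `"region"` (default) to code by anatomical region, or
#'   `"region_hemisphere"` to keep hemisphere in the code.
#' @return Character vector aligned with `cohort` rows.
#' @export
recode_locations <- function(cohort, mode = c("primary_only", "multi_cluster"),
                             by = c("region", "region_hemisphere")) {
  mode <- match.arg(mode)
  by <- match.arg(by)
  cohort <- validate_cohort(cohort)
  locs <- parse_locations(cohort$rssi_locations)
  n_codes <- vapply(locs, nrow, integer(1))
  bad <- which(cohort$rssi_volume_ml > 0 & n_codes == 0L)
  if (length(bad)) {
    abort(sprintf("subject(s) with RSSI volume but no location code: %s",
                  paste(cohort$subject_id[bad], collapse = ", ")))
  }
  vapply(locs, function(l) {
    if (nrow(l) == 0) return("none")
    codes <- if (by == "region") l$region else paste(l$region, l$hemisphere, sep = ",")
    if (mode == "primary_only") codes[[1]] else paste(sort(unique(codes)), collapse = " + ")
  }, character(1))
}
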
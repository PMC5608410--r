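# Cohort-level statistics: Mann-Whitney U, pooled-variance t-test with
# Cohen's d, covariate-matched subgroup selection, standardized ordinary
# least squares, and the nested-model R-squared-change F test.

#' Mann-Whitney U test for two independent samples
#'
#' U is computed from rank sums with midranks for ties. When both samples
#' have at most `exact_max` observations (default 8) the two-sided p-value
#' is obtained by exact enumeration of all group assignments of the pooled
#' sample; otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` decides by sample size.
#' @param exact_max Largest per-group size for the exact mode.
#' @return List with `U` (for sample `a`), `p` (two-sided) and `method`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL, exact_max = 8L) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (length(unique(pooled)) == 1L) {
    warning("all observations tied; p-value set to 1")
    return(list(U = U, p = 1, method = "degenerate"))
  }

  do_exact <- if (is.null(exact)) (n1 <= exact_max && n2 <= exact_max) else exact
  if (do_exact) {
    sel <- utils::combn(N, n1)
    Us <- colSums(matrix(rk[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }

  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("zero variance under ties; p-value set to 1")
    return(list(U = U, p = 1, method = "degenerate"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

#' Cohen's d from group summary statistics
#'
#' `d = (mean2 - mean1) / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1 Summary statistics of the first (reference) group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return Cohen's d (positive when group 2 has the larger mean).
#' @export
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean2 - mean1) / sp
}

#' Two-tailed pooled-variance t-test with Cohen's d
#'
#' Student's t-test for independent samples with pooled variance, plus the
#' standardized mean difference (Cohen's d, sign of `mean(high) -
#' mean(low)`).
#'
#' @param low,high Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p` (two-sided), `d`, `mean_low`, `sd_low`,
#'   `mean_high`, `sd_high`, `n_low`, `n_high`.
#' @export
ttest_cohens_d <- function(low, high) {
  low <- as.numeric(low); high <- as.numeric(high)
  stopifnot(length(low) >= 2, length(high) >= 2)
  n1 <- length(low); n2 <- length(high)
  m1 <- mean(low); m2 <- mean(high)
  s1 <- stats::sd(low); s2 <- stats::sd(high)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled variance is zero")
  se <- sp * sqrt(1 / n1 + 1 / n2)
  tval <- (m2 - m1) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tval), df)
  list(t = tval, df = df, p = p,
       d = cohens_d_pooled(m1, s1, n1, m2, s2, n2),
       mean_low = m1, sd_low = s1, mean_high = m2, sd_high = s2,
       n_low = n1, n_high = n2)
}

#' Standardized ordinary least squares
#'
#' All variables (the outcome, continuous predictors, and 0/1 dummies
#' alike) are z-scored before an ordinary least-squares fit with
#' intercept; the reported coefficients are therefore standardized betas.
#'
#' @param y Numeric outcome vector.
#' @param X Data frame or named list of predictor columns. Logical and
#'   two-level factor columns are converted to 0/1 dummies.
#' @return A `regression_fit`: list with `betas`, `p_values` (per
#'   predictor, two-sided t-tests), `r_squared`, `n`, `predictors`,
#'   `df_residual`, and the standardized outcome `y_std` (retained so
#'   nested comparisons can verify they share observations).
#' @export
standardized_ols <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  stopifnot(nrow(X) == n, n > ncol(X) + 1)
  Xn <- lapply(X, function(col) {
    if (is.logical(col)) col <- as.numeric(col)
    if (is.factor(col)) {
      if (nlevels(col) != 2L) stop("factors must have exactly two levels")
      col <- as.numeric(col) - 1
    }
    if (is.character(col)) {
      u <- sort(unique(col))
      if (length(u) != 2L) stop("character predictors must have two levels")
      col <- as.numeric(col == u[2])
    }
    as.numeric(col)
  })
  sds <- vapply(Xn, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant predictor(s): ", paste(names(Xn)[sds == 0], collapse = ", "))
  }
  Z <- vapply(Xn, function(col) (col - mean(col)) / stats::sd(col),
              numeric(n))
  Z <- matrix(Z, nrow = n, dimnames = list(NULL, names(Xn)))
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1L) {
    dropped <- colnames(Z)[setdiff(seq_len(ncol(Z) + 1L), qrz$pivot[seq_len(qrz$rank)]) - 1L]
    stop("collinear predictor(s): ", paste(dropped, collapse = ", "))
  }
  if (stats::sd(y) == 0) stop("outcome has zero variance")
  y_std <- (y - mean(y)) / stats::sd(y)
  fit <- stats::lm(y_std ~ Z)
  sm <- summary(fit)
  co <- sm$coefficients
  betas <- co[-1, 1]
  pvals <- co[-1, 4]
  names(betas) <- names(pvals) <- colnames(Z)
  structure(list(betas = betas, p_values = pvals,
                 r_squared = sm$r.squared, n = n,
                 predictors = colnames(Z),
                 df_residual = fit$df.residual,
                 y_std = y_std),
            class = "regression_fit")
}

#' Nested-model comparison (R-squared change F test)
#'
#' For nested fits on the same observations, `delta_r2 = R2_2 - R2_1` and
#' `F = (delta_r2 / q) / ((1 - R2_2) / (n - p2 - 1))` with `q` added
#' predictors; the p-value comes from the F distribution with `(q, n - p2
#' - 1)` degrees of freedom. Identical models give `F = 0`, `p = 1`.
#'
#' @param fit1,fit2 `regression_fit` objects from [standardized_ols()];
#'   `fit1`'s predictors must be a subset of `fit2`'s.
#' @return A `nested_comparison`: list with `delta_r2`, `f_change`,
#'   `p_change`, `fit1`, `fit2`.
#' @export
nested_model_test <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "regression_fit"), inherits(fit2, "regression_fit"))
  if (!all(fit1$predictors %in% fit2$predictors)) {
    stop("models are not nested: model 1 predictors are not a subset of model 2's")
  }
  if (fit1$n != fit2$n || !isTRUE(all.equal(fit1$y_std, fit2$y_std))) {
    stop("nested models must be fit on the same observations")
  }
  q <- length(fit2$predictors) - length(fit1$predictors)
  delta <- fit2$r_squared - fit1$r_squared
  if (q == 0L) {
    return(structure(list(delta_r2 = 0, f_change = 0, p_change = 1,
                          fit1 = fit1, fit2 = fit2),
                     class = "nested_comparison"))
  }
  df2 <- fit2$n - length(fit2$predictors) - 1
  f <- (delta / q) / ((1 - fit2$r_squared) / df2)
  p <- stats::pf(f, q, df2, lower.tail = FALSE)
  structure(list(delta_r2 = delta, f_change = f, p_change = p,
                 fit1 = fit1, fit2 = fit2),
            class = "nested_comparison")
}

#' Select WMH-load subgroups matched on covariates
#'
#' Splits a control cohort into lower- and higher-load classes by
#' [classify_wmh_load()] and pairs higher-load subjects 1:1 with
#' lower-load subjects by greedy nearest-neighbour matching on the
#' standardized distance over age, MMSE and ventricle load, within exact
#' strata on sex and cardiovascular disease where feasible (strata are
#' relaxed when a class is exhausted). The `target_n` closest pairs are
#' kept. The balance report gives post-match Mann-Whitney p-values for the
#' continuous covariates and two-proportion tests for sex and CVD.
#'
#' @param cohort A cohort data frame (see [simulate_cohort()]); only
#'   control subjects are used.
#' @param target_n Number of matched pairs (default 21).
#' @return A `matched_pairs`: list with `pairs` (data frame of lower/higher
#'   ids and distances), `balance_report` (data frame of covariate, statistic,
#'   p), `lower_ids`, `higher_ids`.
#' @export
match_subgroups <- function(cohort, target_n = 21L) {
  ctrl <- cohort[cohort$group == "control", , drop = FALSE]
  cls <- classify_wmh_load(ctrl$wmh_pct)
  low <- ctrl[cls == "lower", , drop = FALSE]
  high <- ctrl[cls == "higher", , drop = FALSE]
  if (nrow(low) < target_n || nrow(high) < target_n) {
    stop(sprintf(paste0("insufficient class sizes for matching: %d lower-",
                        "load and %d higher-load subjects available, %d pairs requested"),
                 nrow(low), nrow(high), target_n))
  }
  covs <- c("age", "mmse", "vv_pct")
  pool <- rbind(low[covs], high[covs])
  mu <- colMeans(pool)
  sg <- vapply(pool, stats::sd, numeric(1))
  sg[sg == 0] <- 1
  zl <- sweep(sweep(as.matrix(low[covs]), 2, mu), 2, sg, "/")
  zh <- sweep(sweep(as.matrix(high[covs]), 2, mu), 2, sg, "/")

  used <- rep(FALSE, nrow(low))
  pairs <- data.frame(lower_id = character(0), higher_id = character(0),
                      distance = numeric(0), stratum_exact = logical(0))
  for (i in seq_len(nrow(high))) {
    d <- sqrt(colSums((t(zl) - zh[i, ])^2))
    same <- low$sex == high$sex[i] & low$cvd == high$cvd[i]
    cand <- which(!used & same)
    exact <- TRUE
    if (!length(cand)) {
      cand <- which(!used)
      exact <- FALSE
    }
    if (!length(cand)) break
    j <- cand[which.min(d[cand])]
    used[j] <- TRUE
    pairs <- rbind(pairs, data.frame(lower_id = low$id[j],
                                     higher_id = high$id[i],
                                     distance = d[j],
                                     stratum_exact = exact))
  }
  if (nrow(pairs) < target_n) {
    stop("matching exhausted the lower-load class before reaching target_n")
  }
  pairs <- pairs[order(pairs$distance), , drop = FALSE][seq_len(target_n), ]

  ml <- low[match(pairs$lower_id, low$id), , drop = FALSE]
  mh <- high[match(pairs$higher_id, high$id), , drop = FALSE]
  bal <- lapply(covs, function(v) {
    mw <- mann_whitney_u(ml[[v]], mh[[v]])
    data.frame(covariate = v, statistic = mw$U, p = mw$p)
  })
  prop_p <- function(x1, x2) {
    tab <- rbind(c(sum(x1), length(x1) - sum(x1)),
                 c(sum(x2), length(x2) - sum(x2)))
    if (all(tab[1, ] == tab[2, ])) return(list(stat = 0, p = 1))
    pt <- suppressWarnings(stats::prop.test(tab[, 1], rowSums(tab)))
    list(stat = unname(pt$statistic), p = pt$p.value)
  }
  sx <- prop_p(ml$sex == "M", mh$sex == "M")
  cv <- prop_p(ml$cvd, mh$cvd)
  bal <- rbind(do.call(rbind, bal),
               data.frame(covariate = "sex", statistic = sx$stat, p = sx$p),
               data.frame(covariate = "cvd", statistic = cv$stat, p = cv$p))
  structure(list(pairs = pairs, balance_report = bal,
                 lower_ids = pairs$lower_id, higher_ids = pairs$higher_id),
            class = "matched_pairs")
}

# tract/metric column helpers
tract_metric_cols <- function(cohort) {
  grep("_(md|fa)$", names(cohort), value = TRUE)
}

#' Matched-subgroup tract comparison table
#'
#' One row per tract and metric comparing the matched lower- and
#' higher-load subgroups with the pooled-variance t-test and Cohen's d. No
#' multiple-comparison correction is applied by default.
#'
#' @param cohort Cohort data frame with per-tract `<tract>_md` /
#'   `<tract>_fa` columns.
#' @param pairs A `matched_pairs` from [match_subgroups()].
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Data frame with columns `tract`, `metric`, `mean_low`, `sd_low`,
#'   `mean_high`, `sd_high`, `t`, `p`, `cohens_d`, `significant`.
#' @export
run_table2 <- function(cohort, pairs, p_adjust = "none") {
  stopifnot(inherits(pairs, "matched_pairs"))
  lo <- cohort[match(pairs$lower_ids, cohort$id), , drop = FALSE]
  hi <- cohort[match(pairs$higher_ids, cohort$id), , drop = FALSE]
  cols <- tract_metric_cols(cohort)
  rows <- list()
  for (cl in cols) {
    if (any(!is.finite(lo[[cl]])) || any(!is.finite(hi[[cl]]))) {
      warning(sprintf("missing values in %s; row skipped", cl))
      next
    }
    ts <- ttest_cohens_d(lo[[cl]], hi[[cl]])
    mm <- sub(".*_", "", cl)
    rows[[cl]] <- data.frame(tract = sub("_(md|fa)$", "", cl),
                             metric = toupper(mm),
                             mean_low = ts$mean_low, sd_low = ts$sd_low,
                             mean_high = ts$mean_high, sd_high = ts$sd_high,
                             t = ts$t, p = ts$p, cohens_d = ts$d)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adj < 0.05
  out
}

#' Nested regression table: group effect unadjusted and adjusted for WMH
#'
#' For every tract and metric, model 1 regresses the DTI estimate on group
#' membership and ventricle load; model 2 adds WMH load. Reported per
#' outcome: the standardized group beta and its p in both models, the
#' standardized WMH beta in model 2, both R-squared values, the R-squared
#' change and its F-test p-value. Standardization z-scores all variables,
#' including the group dummy. No multiplicity correction is applied.
#'
#' @param cohort Cohort data frame (both groups).
#' @param extra_covariates Character vector of additional model-1 covariate
#'   columns (e.g. `"mmse"`); none by default.
#' @param alpha Significance level for the flags (default 0.05).
#' @return Data frame with one row per tract x metric.
#' @export
run_table3 <- function(cohort, extra_covariates = character(), alpha = 0.05) {
  stopifnot(all(c("group", "vv_pct", "wmh_pct") %in% names(cohort)))
  grp <- as.numeric(cohort$group == "prodromal_ad")
  cols <- tract_metric_cols(cohort)
  rows <- list()
  for (cl in cols) {
    X1 <- data.frame(group = grp, vv_pct = cohort$vv_pct)
    for (v in extra_covariates) X1[[v]] <- cohort[[v]]
    X2 <- X1
    X2$wmh_pct <- cohort$wmh_pct
    f1 <- standardized_ols(cohort[[cl]], X1)
    f2 <- standardized_ols(cohort[[cl]], X2)
    nc <- nested_model_test(f1, f2)
    rows[[cl]] <- data.frame(
      tract = sub("_(md|fa)$", "", cl),
      metric = toupper(sub(".*_", "", cl)),
      beta_group_m1 = unname(f1$betas["group"]),
      p_group_m1 = unname(f1$p_values["group"]),
      r2_m1 = f1$r_squared,
      beta_group_m2 = unname(f2$betas["group"]),
      p_group_m2 = unname(f2$p_values["group"]),
      beta_wmh_m2 = unname(f2$betas["wmh_pct"]),
      p_wmh_m2 = unname(f2$p_values["wmh_pct"]),
      r2_m2 = f2$r_squared,
      delta_r2 = nc$delta_r2,
      f_change = nc$f_change,
      p_change = nc$p_change)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$sig_group_m1 <- out$p_group_m1 < alpha
  out$sig_group_m2 <- out$p_group_m2 < alpha
  out$sig_wmh_m2 <- out$p_wmh_m2 < alpha
  out$sig_delta_r2 <- out$p_change < alpha
  out
}

#' Demographic comparison table (control vs prodromal AD)
#'
#' Mann-Whitney U tests of the covariates between the two diagnostic
#' groups, mirroring a sample-characteristics table.
#'
#' @param cohort Cohort data frame.
#' @return Data frame with covariate, per-group mean, U and p.
#' @export
run_table1 <- function(cohort) {
  ctrl <- cohort[cohort$group == "control", ]
  ad <- cohort[cohort$group == "prodromal_ad", ]
  vars <- list(age = "age", sex_male = NULL, cvd = NULL, mmse = "mmse",
               abeta_ratio = "abeta_ratio", vv_pct = "vv_pct",
               wmh_pct = "wmh_pct")
  get_num <- function(d, v) {
    switch(v,
           sex_male = as.numeric(d$sex == "M"),
           cvd = as.numeric(d$cvd),
           d[[v]])
  }
  rows <- lapply(names(vars), function(v) {
    x <- get_num(ctrl, v); y <- get_num(ad, v)
    mw <- mann_whitney_u(x, y)
    data.frame(variable = v, mean_control = mean(x), sd_control = stats::sd(x),
               mean_ad = mean(y), sd_ad = stats::sd(y), U = mw$U, p = mw$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
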
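test_that("Mann-Whitney exact mode matches full enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")

  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:6, 4, replace = TRUE)  # ties likely
    b <- sample(1:6, 4, replace = TRUE)
    if (length(unique(c(a, b))) == 1L) next
    r <- mann_whitney_u(a, b)
    o <- oracle_mw_exact(a, b)
    expect_equal(r$U, o$U)
    expect_equal(r$p, o$p)
  }
})

test_that("identical samples give central U and p near 1", {
  x <- c(1, 2, 3, 4, 5)
  r <- mann_whitney_u(x, x)
  expect_equal(r$U, length(x)^2 / 2)
  expect_gte(r$p, 0.9)
  expect_warning(mann_whitney_u(rep(1, 5), rep(1, 4)), "tied")
})

test_that("the normal approximation agrees with the reference implementation", {
  set.seed(6)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  r <- mann_whitney_u(a, b)
  w <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
  # with heavy ties
  a <- sample(1:4, 30, replace = TRUE); b <- sample(1:4, 28, replace = TRUE)
  r <- mann_whitney_u(a, b)
  w <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
})

test_that("Cohen's d follows the pooled formula, including the printed", {
  # printed matched-subgroup means/SDs for left-SLF MD, n = 21 + 21
  d <- cohens_d_pooled(0.73, 0.03, 21, 0.79, 0.06, 21)
  expect_equal(d, 0.06 / sqrt((20 * 0.0009 + 20 * 0.0036) / 40))
  expect_equal(round(d, 4), 1.2649)
})

test_that("the pooled t-test behaves at its symmetry points", {
  x <- c(1, 2, 3, 4)
  r <- ttest_cohens_d(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$d, 0)
  expect_equal(r$p, 1)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(12, 1)
  r1 <- ttest_cohens_d(a, b)
  r2 <- ttest_cohens_d(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$d, -r2$d)
  expect_equal(r1$p, r2$p)
  # matches the reference pooled-variance t-test
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(r1$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r1$p, tt$p.value, tolerance = 1e-12)
  expect_error(ttest_cohens_d(c(1, 1), c(1, 1)), "zero")
})

test_that("standardized OLS matches the normal-equations oracle", {
  set.seed(8)
  n <- 200
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), g = rbinom(n, 1, 0.4))
  y <- 0.4 * X$x1 - 0.2 * X$x2 + 0.3 * X$g + rnorm(n)
  fit <- standardized_ols(y, X)
  o <- oracle_std_ols(y, X)
  expect_equal(unname(fit$betas), unname(o$betas), tolerance = 1e-10)
  expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
})

test_that("standardized OLS recovers known generative coefficients", {
  set.seed(9)
  n <- 10000
  z1 <- rnorm(n); z2 <- rnorm(n)
  y <- 0.5 * z1 + 0.3 * z2 + rnorm(n, sd = sqrt(1 - 0.25 - 0.09))
  fit <- standardized_ols(y, data.frame(z1 = z1, z2 = z2))
  expect_lt(abs(fit$betas["z1"] - 0.5), 0.02)
  expect_lt(abs(fit$betas["z2"] - 0.3), 0.02)
})

test_that("standardized betas are scale invariant and edge cases error", {
  set.seed(10)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- X$a - X$b + rnorm(n)
  f1 <- standardized_ols(y, X)
  X2 <- X; X2$a <- X2$a * 1000
  f2 <- standardized_ols(y, X2)
  expect_equal(f1$betas, f2$betas, tolerance = 1e-10)
  # perfect fit
  fp <- suppressWarnings(standardized_ols(X$a, data.frame(a = X$a)))
  expect_equal(unname(fp$betas), 1, tolerance = 1e-12)
  expect_equal(fp$r_squared, 1, tolerance = 1e-12)
  expect_error(standardized_ols(y, data.frame(a = X$a, c = rep(2, n))),
               "constant")
  expect_error(standardized_ols(y, data.frame(a = X$a, b = 2 * X$a)),
               "collinear")
})

test_that("the F-change test matches the SSE-decomposition oracle", {
  set.seed(11)
  n <- 120
  X1 <- data.frame(g = rbinom(n, 1, 0.5), v = rnorm(n))
  X2 <- X1; X2$w <- rnorm(n) + 0.5 * X1$g
  y <- 0.3 * X1$g + 0.2 * X2$w + rnorm(n)
  f1 <- standardized_ols(y, X1)
  f2 <- standardized_ols(y, X2)
  nc <- nested_model_test(f1, f2)
  o <- oracle_f_change(y, X1, X2)
  expect_equal(nc$f_change, o$f, tolerance = 1e-10)
  expect_equal(nc$p_change, o$p, tolerance = 1e-10)
  expect_equal(nc$delta_r2, o$delta_r2, tolerance = 1e-10)
  expect_gte(nc$delta_r2, 0)
  # identity case
  same <- nested_model_test(f1, f1)
  expect_equal(same$delta_r2, 0)
  expect_equal(same$f_change, 0)
  expect_equal(same$p_change, 1)
  # non-nested models error
  fx <- standardized_ols(y, data.frame(other = rnorm(n)))
  expect_error(nested_model_test(f1, fx), "nested")
})

test_that("the F-change p-value is uniform under the null", {
  set.seed(12)
  n <- 60
  reps <- 1000
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- rbinom(n, 1, 0.5)
    y <- 0.3 * g + rnorm(n)
    f1 <- standardized_ols(y, data.frame(g = g))
    f2 <- standardized_ols(y, data.frame(g = g, noise = rnorm(n)))
    nc <- nested_model_test(f1, f2)
    expect_gte(nc$delta_r2, 0)
    ps[r] <- nc$p_change
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("matching returns target_n zero-distance pairs for clone classes", {
  base <- data.frame(age = rep(70, 21), mmse = rep(29, 21),
                     vv_pct = rep(2, 21), sex = rep("M", 21),
                     cvd = rep(FALSE, 21))
  co <- rbind(cbind(base, wmh_pct = 0.2), cbind(base, wmh_pct = 1.5))
  co$group <- "control"
  co$id <- sprintf("s%02d", seq_len(nrow(co)))
  # degenerate all-tied covariates legitimately warn inside the balance tests
  mp <- suppressWarnings(match_subgroups(co, target_n = 21))
  expect_equal(nrow(mp$pairs), 21L)
  expect_equal(max(mp$pairs$distance), 0)
  expect_true(all(mp$balance_report$p == 1))
})

test_that("matching errors report insufficient class sizes", {
  co <- simulate_cohort(cohort_spec(n_control = 30, n_ad = 5, seed = 1))
  expect_error(match_subgroups(co, target_n = 21), "insufficient|exhausted")
})

test_that("matched subgroups are balanced across simulated cohorts", {
  ok <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_spec(seed = s))
    mp <- match_subgroups(co)
    all(mp$balance_report$p > 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the matched-subgroup table has one row per tract and metric", {
  co <- simulate_cohort(cohort_spec(seed = 3))
  mp <- match_subgroups(co)
  t2 <- run_table2(co, mp)
  expect_equal(nrow(t2), 16L)
  expect_setequal(unique(t2$metric), c("MD", "FA"))
  # d sign convention: higher-load minus lower-load
  slf <- t2[t2$tract == "slf_l" & t2$metric == "MD", ]
  expect_equal(sign(slf$cohens_d), sign(slf$mean_high - slf$mean_low))
})

test_that("MD effect sizes rank by tract susceptibility", {
  # the generative susceptibility ordering (SLF > DC > CST ~ VC) should be
  # recovered by the hemisphere-averaged |d| ranking in most replicates
  hits <- vapply(1:200, function(s) {
    co <- simulate_cohort(cohort_spec(seed = 1000 + s))
    t2 <- run_table2(co, match_subgroups(co))
    md <- t2[t2$metric == "MD", ]
    fam <- sub("_(r|l)$", "", md$tract)
    dbar <- tapply(abs(md$cohens_d), fam, mean)
    dbar["slf"] == max(dbar) && dbar["dc"] > dbar["vc"]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("the matched contrast keeps its nominal size under the null", {
  ps <- unlist(lapply(1:100, function(s) {
    co <- simulate_cohort(null_cohort_spec(seed = 2000 + s))
    run_table2(co, match_subgroups(co))$p
  }))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("the nested regression table carries the adjustment columns", {
  co <- simulate_cohort(confound_scenario_spec(seed = 4))
  t3 <- run_table3(co)
  expect_equal(nrow(t3), 16L)
  expect_true(all(c("beta_group_m1", "beta_group_m2", "beta_wmh_m2",
                    "delta_r2", "f_change", "p_change") %in% names(t3)))
  expect_true(all(t3$delta_r2 >= 0))
  expect_true(all(t3$r2_m2 >= t3$r2_m1))
  # the designed mediation pattern on this single replicate
  slf <- t3[t3$tract == "slf_l" & t3$metric == "MD", ]
  expect_true(slf$sig_group_m1)
  expect_true(slf$sig_wmh_m2)
})

test_that("demographic comparisons flag the designed group differences", {
  co <- simulate_cohort(cohort_spec(seed = 5))
  t1 <- run_table1(co)
  expect_true(all(c("mmse", "abeta_ratio", "wmh_pct") %in% t1$variable))
  expect_lt(t1$p[t1$variable == "mmse"], 0.001)
  expect_lt(t1$p[t1$variable == "abeta_ratio"], 0.001)
  expect_lt(t1$p[t1$variable == "wmh_pct"], 0.05)
  expect_gt(t1$p[t1$variable == "age"], 0.05)
})
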
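test_that("design matrix rows follow the log-linear DTI convention", {
  X <- dti_design_matrix(0, c(0, 0, 0))
  expect_equal(drop(X), c(1, 0, 0, 0, 0, 0, 0))
  X <- dti_design_matrix(1, c(1, 0, 0))
  expect_equal(drop(X), c(1, -1, 0, 0, 0, 0, 0))
  sch <- dwi_scheme()
  expect_equal(dim(dti_design_matrix(sch$bvals, sch$bvecs)), c(65L, 7L))
  # general row against the quadratic form
  g <- c(1, 2, 2) / 3
  X <- dti_design_matrix(1.5, g)
  expect_equal(drop(X),
               c(1, -1.5 * g[1]^2, -1.5 * g[2]^2, -1.5 * g[3]^2,
                 -3 * g[1] * g[2], -3 * g[1] * g[3], -3 * g[2] * g[3]))
})

test_that("WLLS recovers arbitrary SPD tensors exactly from noise-free data", {
  dm <- c(6L, 6L, 6L)
  set.seed(2)
  tens <- array(0, c(dm, 6L))
  for (v in seq_len(prod(dm))) {
    ijk <- arrayInd(v, dm)
    tens[ijk[1], ijk[2], ijk[3], ] <- random_spd()$vec * 0.3
  }
  tf <- tensor_field(tens, array(400, dm), array(TRUE, dm), 2)
  acq <- simulate_dwi(tf, snr_b0 = Inf)
  fit <- fit_wlls(acq)
  expect_true(all(fit$valid_mask))
  expect_lt(max(abs(fit$tensor - tens)), 1e-8)
  expect_lt(max(abs(fit$s0 - 400)), 1e-6)
})

test_that("WLLS median MD matches a nonlinear least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  n <- 1000L
  ev <- c(1.4, 0.45, 0.45)
  t6 <- tensor6_along(c(1, 0, 0), ev)
  dm <- c(n, 1L, 1L)
  tens <- array(rep(t6, each = n), c(dm, 6L))
  tf <- tensor_field(tens, array(500, dm), array(TRUE, dm), 2)
  acq <- simulate_dwi(tf, snr_b0 = 30, seed = 6)
  fit <- fit_wlls(acq)
  ef <- eigendecompose(fit)
  maps <- scalar_maps(ef)
  md_wlls <- maps$md$values[, 1, 1]

  X <- dti_design_matrix(acq$bvals, acq$bvecs)
  sig <- matrix(acq$signal, n, length(acq$bvals))
  md_nlls <- vapply(seq_len(n), function(v) {
    y <- sig[v, ]
    df <- as.data.frame(X)
    names(df) <- paste0("x", 1:7)
    df$y <- y
    start <- as.list(c(log(500), t6))
    names(start) <- paste0("b", 1:7)
    fml <- y ~ exp(b1 * x1 + b2 * x2 + b3 * x3 + b4 * x4 +
                     b5 * x5 + b6 * x6 + b7 * x7)
    ft <- minpack.lm::nlsLM(fml, data = df, start = start,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
    co <- stats::coef(ft)
    (co["b2"] + co["b3"] + co["b4"]) / 3  # MD = trace/3
  }, numeric(1))
  expect_equal(stats::median(md_wlls), stats::median(md_nlls),
               tolerance = 0.02)
})

test_that("degenerate voxels are invalidated, never raised as errors", {
  dm <- c(2L, 2L, 2L)
  tens <- array(rep(tensor6_along(c(1, 0, 0), c(1.4, 0.45, 0.45)),
                    each = prod(dm)), c(dm, 6L))
  tf <- tensor_field(tens, array(300, dm), array(TRUE, dm), 2)
  acq <- simulate_dwi(tf, snr_b0 = Inf)
  acq$signal[1, 1, 1, ] <- 0           # dead voxel
  fit <- fit_wlls(acq)
  expect_false(fit$valid_mask[1, 1, 1])
  expect_true(all(fit$valid_mask[-1]))
})

test_that("a rank-deficient encoding raises an explicit error", {
  dm <- c(2L, 2L, 2L)
  sig <- array(100, c(dm, 8L))
  # all gradients along x: cannot resolve off-axis components
  bvecs <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 7), ncol = 3, byrow = TRUE))
  acq <- diffusion_acquisition(sig, c(0, rep(1, 7)), bvecs, 2)
  expect_error(fit_wlls(acq), "rank-deficient")
})

test_that("eigendecomposition is exact on diagonal and isotropic tensors", {
  dm <- c(2L, 1L, 1L)
  tens <- array(0, c(dm, 6L))
  tens[1, 1, 1, ] <- c(1.7, 0.3, 0.2, 0, 0, 0)
  tens[2, 1, 1, ] <- c(0.7, 0.7, 0.7, 0, 0, 0)
  tf <- tensor_field(tens, array(1, dm), array(TRUE, dm), 2)
  ef <- eigendecompose(tf)
  expect_equal(ef$eigenvalues[1, 1, 1, ], c(1.7, 0.3, 0.2))
  expect_equal(ef$eigenvalues[2, 1, 1, ], c(0.7, 0.7, 0.7))
  expect_equal(ef$principal_direction[1, 1, 1, ], c(1, 0, 0))
})

test_that("eigenvalues are rotation invariant", {
  set.seed(3)
  lam <- c(1.7, 0.3, 0.2)
  for (r in 1:20) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    D <- Q %*% diag(lam) %*% t(Q)
    dm <- c(1L, 1L, 1L)
    tens <- array(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                  c(dm, 6L))
    ef <- eigendecompose(tensor_field(tens, array(1, dm), array(TRUE, dm), 2))
    expect_equal(ef$eigenvalues[1, 1, 1, ], lam, tolerance = 1e-10)
    # sign convention: first non-negligible component non-negative
    v1 <- ef$principal_direction[1, 1, 1, ]
    nz <- which(abs(v1) > 1e-12)[1]
    expect_gte(v1[nz], 0)
  }
})

test_that("MD and FA maps follow the closed-form eigenvalue expressions", {
  expect_equal(md_from_eigenvalues(1, 1, 1), 1)
  expect_equal(fa_from_eigenvalues(1, 1, 1), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  expect_equal(fa_from_eigenvalues(0, 0, 0), 0)
  # frozen from the closed-form formula at lambda = (1.7, 0.3, 0.2)
  expect_equal(md_from_eigenvalues(1.7, 0.3, 0.2), 0.7333333333, tolerance = 1e-9)
  expect_equal(fa_from_eigenvalues(1.7, 0.3, 0.2), 0.835868109625, tolerance = 1e-9)
})

test_that("negative eigenvalues are clamped for maps but retained raw", {
  dm <- c(1L, 1L, 1L)
  tens <- array(c(1, 0.5, -0.1, 0, 0, 0), c(dm, 6L))
  ef <- eigendecompose(tensor_field(tens, array(1, dm), array(TRUE, dm), 2))
  expect_lt(min(ef$eigenvalues), 0)
  maps <- scalar_maps(ef)
  expect_equal(maps$md$values[1, 1, 1], 0.5)  # (1 + 0.5 + 0) / 3
  expect_gte(maps$fa$values[1, 1, 1], 0)
  expect_lte(maps$fa$values[1, 1, 1], 1)
})

test_that("FA stays in [0,1] and MD equals trace/3 on random SPD voxels", {
  set.seed(4)
  n <- 2000L
  dm <- c(n, 1L, 1L)
  tens <- array(0, c(dm, 6L))
  tr <- numeric(n)
  for (v in seq_len(n)) {
    sp <- random_spd()
    tens[v, 1, 1, ] <- sp$vec
    tr[v] <- sum(diag(sp$mat))
  }
  ef <- eigendecompose(tensor_field(tens, array(1, dm), array(TRUE, dm), 2))
  maps <- scalar_maps(ef)
  expect_true(all(maps$fa$values >= 0 & maps$fa$values <= 1))
  expect_lt(max(abs(maps$md$values[, 1, 1] - tr / 3)), 1e-12)
})

test_that("reweighting does not inflate variance relative to OLS on logs", {
  # heteroscedastic replicates of one voxel: log-domain noise scales as
  # 1/signal, so the weighted fit should be at least as efficient
  n <- 1000L
  t6 <- tensor6_along(c(1, 0, 0), c(1.4, 0.45, 0.45))
  dm <- c(n, 1L, 1L)
  tens <- array(rep(t6, each = n), c(dm, 6L))
  tf <- tensor_field(tens, array(500, dm), array(TRUE, dm), 2)
  acq <- simulate_dwi(tf, snr_b0 = 20, seed = 9)
  f_wlls <- fit_wlls(acq, weighting_passes = 1L)
  f_ols <- fit_wlls(acq, weighting_passes = 0L)
  v_wlls <- stats::var(f_wlls$tensor[, 1, 1, 1])
  v_ols <- stats::var(f_ols$tensor[, 1, 1, 1])
  expect_lte(v_wlls, v_ols * 1.02)
})
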
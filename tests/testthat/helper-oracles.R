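# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive quantities from first principles (pairwise counts,
# normal equations, sums of squares, closed-form formulas) so that they
# share no code with the implementation paths they check.

# Mann-Whitney U by direct pairwise counting, two-sided p by exhaustive
# permutation of the group labels.
oracle_mw_exact <- function(a, b) {
  count_u <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) {
      if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
    }
    u
  }
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_obs <- count_u(a, b)
  mu <- n1 * n2 / 2
  sel <- utils::combn(n1 + n2, n1)
  us <- apply(sel, 2, function(s) count_u(pooled[s], pooled[-s]))
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

# standardized OLS via the normal equations
oracle_std_ols <- function(y, X) {
  Z <- vapply(X, function(c) (c - mean(c)) / stats::sd(c), numeric(length(y)))
  ys <- (y - mean(y)) / stats::sd(y)
  Xm <- cbind(intercept = 1, Z)
  b <- solve(t(Xm) %*% Xm, t(Xm) %*% ys)
  res <- ys - Xm %*% b
  sse <- sum(res^2)
  sst <- sum((ys - mean(ys))^2)
  list(betas = b[-1, 1], r_squared = 1 - sse / sst, sse = sse)
}

# nested-model F test from raw sums of squared errors
oracle_f_change <- function(y, X1, X2) {
  f1 <- oracle_std_ols(y, X1)
  f2 <- oracle_std_ols(y, X2)
  n <- length(y)
  q <- length(X2) - length(X1)
  df2 <- n - length(X2) - 1
  f <- ((f1$sse - f2$sse) / q) / (f2$sse / df2)
  list(f = f, p = stats::pf(f, q, df2, lower.tail = FALSE),
       delta_r2 = f2$r_squared - f1$r_squared)
}

# random symmetric positive-definite 3x3 tensor (as 6-vector and matrix)
random_spd <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  D <- crossprod(A) + diag(3) * 1e-3
  list(mat = D, vec = c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]))
}

# tensor 6-vector (xx,yy,zz,xy,xz,yz) for eigenvalues ev along unit axis e1
tensor6_along <- function(e1, ev) {
  ref <- if (abs(e1[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  e2 <- c(e1[2] * ref[3] - e1[3] * ref[2],
          e1[3] * ref[1] - e1[1] * ref[3],
          e1[1] * ref[2] - e1[2] * ref[1])
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  D <- ev[1] * outer(e1, e1) + ev[2] * outer(e2, e2) + ev[3] * outer(e3, e3)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# hand-built tensor field: direction array (x,y,z,3) of unit axes, logical
# `inside` mask, NAWM eigenvalues inside and isotropic background outside
make_tensor_field_from_dirs <- function(dirs, inside, ev = c(1.4, 0.45, 0.45),
                                        bg = 0.8, voxel_size = 2) {
  dm <- dim(inside)
  tens <- array(0, c(dm, 6L))
  s0 <- array(500, dm)
  for (v in seq_len(prod(dm))) {
    ijk <- arrayInd(v, dm)
    if (inside[v]) {
      d <- dirs[ijk[1], ijk[2], ijk[3], ]
      t6 <- tensor6_along(d, ev)
    } else {
      t6 <- c(bg, bg, bg, 0, 0, 0)
    }
    tens[ijk[1], ijk[2], ijk[3], ] <- t6
  }
  tensor_field(tens, s0, array(TRUE, dm), voxel_size)
}

# a random connected-ish blob mask grown from a seed voxel
random_blob_mask <- function(dm, n_vox = 20L) {
  m <- array(FALSE, dm)
  cur <- matrix(sapply(dm, function(d) sample(3:(d - 2), 1)), 1)
  m[cur] <- TRUE
  while (sum(m) < n_vox) {
    idx <- which(m, arr.ind = TRUE)
    p <- idx[sample.int(nrow(idx), 1), ]
    q <- p + sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    if (all(q >= 1) && all(q <= dm)) m[q[1], q[2], q[3]] <- TRUE
  }
  m
}

# brute-force streamline filter: per-vertex membership in masks
oracle_segment <- function(streams, and_roi, not_shell) {
  dm <- dim(and_roi)
  keep <- logical(length(streams$streamlines))
  for (s in seq_along(streams$streamlines)) {
    line <- streams$streamlines[[s]]
    hit_and <- FALSE; hit_not <- FALSE
    for (r in seq_len(nrow(line))) {
      ijk <- round(solve(streams$affine) %*% c(line[r, ], 1))[1:3] + 1
      if (any(ijk < 1) || any(ijk > dm)) next
      if (and_roi[ijk[1], ijk[2], ijk[3]]) hit_and <- TRUE
      if (not_shell[ijk[1], ijk[2], ijk[3]]) hit_not <- TRUE
    }
    keep[s] <- hit_and && !hit_not
  }
  keep
}
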
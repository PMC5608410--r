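# Diffusion tensor estimation. Units: diffusivities in um^2/ms, b-values in
# ms/um^2 (so b = 1000 s/mm^2 is stored as 1.0), distances in mm.

#' Per-voxel diffusion tensor field
#'
#' @param tensor 4-D array `(x, y, z, 6)` of tensor components in the order
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`, um^2/ms.
#' @param s0 3-D array of non-diffusion-weighted amplitudes.
#' @param valid_mask 3-D logical array of voxels with a usable tensor.
#' @param voxel_size Voxel edge length(s), mm.
#' @param affine Optional 4x4 voxel-to-world affine (defaults to the
#'   diagonal affine implied by `voxel_size`).
#' @return A `tensor_field` object.
#' @export
tensor_field <- function(tensor, s0, valid_mask, voxel_size, affine = NULL) {
  stopifnot(length(dim(tensor)) == 4L, dim(tensor)[4] == 6L,
            identical(dim(s0), dim(tensor)[1:3]),
            identical(dim(valid_mask), dim(tensor)[1:3]))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(affine)) affine <- vox_affine(voxel_size)
  structure(list(tensor = tensor, s0 = s0, valid_mask = valid_mask,
                 voxel_size = voxel_size, affine = affine),
            class = "tensor_field")
}

#' Log-linear DTI design matrix
#'
#' Row `i` is `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz,
#' -2b gy gz]`, so that the parameter vector is
#' `[ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]`.
#'
#' @param bvals Numeric vector of b-values in ms/um^2.
#' @param bvecs Matrix (n x 3) of unit gradient directions.
#' @return An n x 7 design matrix.
#' @export
dti_design_matrix <- function(bvals, bvecs) {
  bvecs <- rbind3(bvecs)
  stopifnot(length(bvals) == nrow(bvecs))
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2,
        -bvals * g[, 2]^2,
        -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor by weighted linear least squares
#'
#' Heteroscedasticity-corrected linear least squares in two passes: pass 1
#' is ordinary least squares on the log-signals; pass 2 re-solves each voxel
#' with weights equal to the squared pass-1 predicted signals, which undoes
#' the variance distortion introduced by the log transform. Signals at or
#' below zero are clamped to a machine-epsilon-scaled floor before taking
#' logs; a voxel with more than half of its measurements clamped, or a
#' non-finite solution, is marked invalid (never an error).
#'
#' @param acq A [diffusion_acquisition()].
#' @param mask Optional 3-D logical array restricting the fit.
#' @param weighting_passes Number of reweighting passes beyond the initial
#'   log-linear solve (default 1, i.e. two passes in total; 0 gives plain
#'   ordinary least squares on logs).
#' @return A [tensor_field()].
#' @export
fit_wlls <- function(acq, mask = NULL, weighting_passes = 1L) {
  stopifnot(inherits(acq, "diffusion_acquisition"))
  dm <- dim(acq$signal)[1:3]
  nmeas <- dim(acq$signal)[4]
  if (is.null(mask)) mask <- array(TRUE, dm)
  stopifnot(identical(dim(mask), dm))

  X <- dti_design_matrix(acq$bvals, acq$bvecs)
  if (qr(X)$rank < 7L) {
    stop("rank-deficient diffusion encoding: the acquisition cannot ",
         "determine all 6 tensor components plus S0")
  }
  if (nmeas < 7L) stop("at least 7 measurements are required")

  idx <- which(mask)
  sig <- matrix(acq$signal, prod(dm), nmeas)[idx, , drop = FALSE]

  # clamp non-positive signals; invalidate voxels dominated by clamping
  floor_val <- .Machine$double.eps * pmax(apply(sig, 1, max), 1)
  n_clamped <- rowSums(sig <= 0)
  bad <- n_clamped > nmeas / 2
  sig_cl <- pmax(sig, floor_val)
  Y <- log(sig_cl)

  # pass 1: ordinary least squares on logs, shared design across voxels
  XtX <- crossprod(X)
  B <- t(solve(XtX, t(X) %*% t(Y)))  # nvox x 7

  passes <- as.integer(weighting_passes)
  if (passes > 0) {
    for (p in seq_len(passes)) {
      pred <- B %*% t(X)           # predicted log-signal
      W <- exp(2 * pred)           # squared predicted signals
      for (v in seq_len(nrow(B))) {
        if (bad[v]) next
        w <- W[v, ]
        Xw <- X * w
        A <- crossprod(Xw, X)
        bhat <- tryCatch(solve(A, crossprod(Xw, Y[v, ])),
                         error = function(e) rep(NA_real_, 7))
        B[v, ] <- bhat
      }
    }
  }

  ok <- !bad & apply(is.finite(B), 1, all)

  tensor <- array(0, c(dm, 6L))
  s0 <- array(0, dm)
  valid <- array(FALSE, dm)
  tmat <- matrix(tensor, prod(dm), 6)
  tmat[idx[ok], ] <- B[ok, 2:7, drop = FALSE]
  tensor <- array(tmat, c(dm, 6L))
  s0[idx[ok]] <- exp(B[ok, 1])
  valid[idx[ok]] <- TRUE

  tensor_field(tensor, s0, valid, acq$voxel_size, acq$affine)
}

#' Eigendecompose a tensor field
#'
#' Sorted real eigenvalues (descending) of the symmetric per-voxel tensor
#' and the principal eigenvector, with its sign unified so that the first
#' non-negligible component is non-negative.
#'
#' @param tf A [tensor_field()].
#' @return An `eigen_field`: list with `eigenvalues` (x,y,z,3),
#'   `principal_direction` (x,y,z,3), `valid_mask`, `voxel_size`, `affine`,
#'   and the source `tensor` (kept for trilinear direction interpolation
#'   during tracking).
#' @export
eigendecompose <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dm <- dim(tf$s0)
  nvox <- prod(dm)
  tmat <- matrix(tf$tensor, nvox, 6)
  evals <- matrix(NA_real_, nvox, 3)
  evecs <- matrix(NA_real_, nvox, 3)
  for (v in which(tf$valid_mask)) {
    D <- matrix(c(tmat[v, 1], tmat[v, 4], tmat[v, 5],
                  tmat[v, 4], tmat[v, 2], tmat[v, 6],
                  tmat[v, 5], tmat[v, 6], tmat[v, 3]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    evals[v, ] <- e$values
    v1 <- e$vectors[, 1]
    nz <- which(abs(v1) > 1e-12)
    if (length(nz) && v1[nz[1]] < 0) v1 <- -v1
    evecs[v, ] <- v1
  }
  structure(list(eigenvalues = array(evals, c(dm, 3L)),
                 principal_direction = array(evecs, c(dm, 3L)),
                 valid_mask = tf$valid_mask,
                 tensor = tf$tensor,
                 voxel_size = tf$voxel_size, affine = tf$affine),
            class = "eigen_field")
}

#' Mean diffusivity from eigenvalues
#' @param l1,l2,l3 Eigenvalues (vectors or arrays), um^2/ms.
#' @return `(l1 + l2 + l3) / 3`, same shape as the inputs.
#' @export
md_from_eigenvalues <- function(l1, l2, l3) (l1 + l2 + l3) / 3

#' Fractional anisotropy from eigenvalues
#'
#' `sqrt(((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / 2) / sqrt(l1^2+l2^2+l3^2)`,
#' defined as 0 when all eigenvalues are 0.
#'
#' @inheritParams md_from_eigenvalues
#' @return FA, same shape as the inputs, in `[0, 1]` for non-negative input.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  num <- sqrt(0.5 * ((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2))
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- ifelse(den > 0, num / den, 0)
  fa
}

#' A scalar (MD or FA) volume
#' @param values 3-D numeric array.
#' @param kind `"MD"` or `"FA"`.
#' @param valid_mask 3-D logical array.
#' @param voxel_size Voxel size, mm.
#' @param affine Optional 4x4 affine.
#' @return A `scalar_volume` object.
#' @export
scalar_volume <- function(values, kind = c("MD", "FA"), valid_mask,
                          voxel_size, affine = NULL) {
  kind <- match.arg(kind)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(affine)) affine <- vox_affine(voxel_size)
  structure(list(values = values, kind = kind, valid_mask = valid_mask,
                 voxel_size = voxel_size, affine = affine),
            class = "scalar_volume")
}

#' MD and FA maps from an eigen field
#'
#' Negative eigenvalues (possible under noise) are clamped to 0 for the
#' map computation only; the raw eigenvalues in the `eigen_field` are left
#' untouched. Invalid voxels get 0.
#'
#' @param ef An `eigen_field` from [eigendecompose()].
#' @return A list with `md` and `fa` [scalar_volume()]s.
#' @export
scalar_maps <- function(ef) {
  stopifnot(inherits(ef, "eigen_field"))
  dm <- dim(ef$valid_mask)
  ev <- matrix(ef$eigenvalues, prod(dm), 3)
  ev[!ef$valid_mask, ] <- 0
  ev[ev < 0] <- 0
  md <- array(md_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3]), dm)
  fa <- array(fa_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3]), dm)
  md[!ef$valid_mask] <- 0
  fa[!ef$valid_mask] <- 0
  list(md = scalar_volume(md, "MD", ef$valid_mask, ef$voxel_size, ef$affine),
       fa = scalar_volume(fa, "FA", ef$valid_mask, ef$voxel_size, ef$affine))
}
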
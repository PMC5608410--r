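# Diffusion-weighted signal simulation: monoexponential tensor model with
# Rician magnitude noise.

#' A 4-D diffusion-weighted acquisition
#'
#' @param signal 4-D non-negative array `(x, y, z, measurement)`.
#' @param bvals Per-measurement b-values in ms/um^2 (1000 s/mm^2 = 1.0).
#' @param bvecs Per-measurement gradient directions (n x 3); directions for
#'   b > 0 must be unit-norm (non-unit vectors are normalized with a
#'   warning).
#' @param voxel_size Voxel size, mm.
#' @param affine Optional 4x4 voxel-to-world affine.
#' @return A `diffusion_acquisition` object.
#' @export
diffusion_acquisition <- function(signal, bvals, bvecs, voxel_size,
                                  affine = NULL) {
  stopifnot(length(dim(signal)) == 4L)
  bvecs <- rbind3(bvecs)
  nmeas <- dim(signal)[4]
  if (length(bvals) != nmeas || nrow(bvecs) != nmeas) {
    stop("bvals/bvecs length does not match the number of volumes")
  }
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  if (nmeas < 7L || !any(bvals == 0)) {
    stop("need at least 7 measurements including one b=0 volume")
  }
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    warning("non-unit gradient directions were normalized")
    bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(affine)) affine <- vox_affine(voxel_size)
  structure(list(signal = signal, bvals = as.numeric(bvals), bvecs = bvecs,
                 voxel_size = voxel_size, affine = affine),
            class = "diffusion_acquisition")
}

#' Default diffusion encoding scheme
#'
#' One b=0 volume plus `n_dirs` directions at `bval` (default 64 directions
#' at b = 1 ms/um^2, i.e. 1000 s/mm^2). Directions are spread over the
#' sphere by the spherical Fibonacci construction, which gives a nearly
#' uniform, deterministic point set.
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param bval b-value of the weighted volumes, ms/um^2.
#' @param n_b0 Number of b=0 volumes.
#' @return List with `bvals` and `bvecs`.
#' @export
dwi_scheme <- function(n_dirs = 64L, bval = 1, n_b0 = 1L) {
  stopifnot(n_dirs >= 6L, bval > 0, n_b0 >= 1L)
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  dimnames(bvecs) <- NULL
  list(bvals = bvals, bvecs = bvecs)
}

#' Simulate DWI signals from a ground-truth tensor field
#'
#' Noise-free signal `S(b, g) = S0 * exp(-b g' D g)` per voxel, with
#' optional Rician noise: `|S + n1 + i n2|` with independent Gaussian
#' `n1, n2` of standard deviation `sigma = mean(S0 over the brain) /
#' snr_b0`. With `snr_b0 = Inf` the exact model signals are returned.
#'
#' @param truth A [tensor_field()] holding the ground-truth tensors and S0.
#' @param scheme Encoding scheme from [dwi_scheme()] (default: 1 b=0 + 64
#'   directions at b = 1 ms/um^2).
#' @param snr_b0 Signal-to-noise ratio at b=0 (`Inf` for noise-free).
#' @param seed RNG seed for the noise draw.
#' @return A [diffusion_acquisition()].
#' @export
simulate_dwi <- function(truth, scheme = dwi_scheme(), snr_b0 = Inf,
                         seed = 1L) {
  stopifnot(inherits(truth, "tensor_field"))
  bvals <- scheme$bvals
  bvecs <- rbind3(scheme$bvecs)
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    warning("non-unit gradient directions were normalized")
    bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  }

  dm <- dim(truth$s0)
  nvox <- prod(dm)
  nmeas <- length(bvals)
  Dmat <- matrix(truth$tensor, nvox, 6)
  # quadratic form coefficients per measurement
  Q <- cbind(bvals * bvecs[, 1]^2,
             bvals * bvecs[, 2]^2,
             bvals * bvecs[, 3]^2,
             2 * bvals * bvecs[, 1] * bvecs[, 2],
             2 * bvals * bvecs[, 1] * bvecs[, 3],
             2 * bvals * bvecs[, 2] * bvecs[, 3])
  S <- as.vector(truth$s0) * exp(-Dmat %*% t(Q))

  if (is.finite(snr_b0)) {
    s0_brain <- truth$s0[truth$valid_mask]
    sigma <- mean(s0_brain) / snr_b0
    S <- with_seed(child_seed(seed, 2L), {
      n1 <- matrix(stats::rnorm(nvox * nmeas, sd = sigma), nvox, nmeas)
      n2 <- matrix(stats::rnorm(nvox * nmeas, sd = sigma), nvox, nmeas)
      sqrt((S + n1)^2 + n2^2)
    })
  }

  diffusion_acquisition(array(S, c(dm, nmeas)), bvals, bvecs,
                        truth$voxel_size, truth$affine)
}
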
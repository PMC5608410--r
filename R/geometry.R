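# Coordinate conventions used throughout the package:
# voxel indices are 0-based, world coordinates are in mm, a voxel "owns" the
# half-open cube centred on it (ownership by rounding at voxel centres), and
# the voxel->world map is a NIfTI-style 4x4 affine.

#' Build a diagonal voxel-to-world affine
#'
#' Maps 0-based voxel index `(i,j,k)` to world mm `(i,j,k) * voxel_size`.
#'
#' @param voxel_size Numeric length-3 (or scalar) voxel edge lengths in mm.
#' @return A 4x4 affine matrix.
#' @export
vox_affine <- function(voxel_size) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxel_size, 3L)
  A
}

#' Convert world coordinates to fractional voxel indices
#'
#' @param pts Numeric matrix (n x 3) or length-3 vector of world mm points.
#' @param affine 4x4 voxel-to-world affine.
#' @return n x 3 matrix of 0-based fractional voxel coordinates.
#' @export
world_to_voxel <- function(pts, affine) {
  pts <- rbind3(pts)
  ph <- cbind(pts, 1)
  out <- t(solve(affine) %*% t(ph))
  out[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel indices to world coordinates
#'
#' @param ijk Numeric matrix (n x 3) or length-3 vector of 0-based indices.
#' @param affine 4x4 voxel-to-world affine.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind3(ijk)
  ph <- cbind(ijk, 1)
  out <- t(affine %*% t(ph))
  out[, 1:3, drop = FALSE]
}

#' Containing voxel of world points
#'
#' Voxel ownership is half-open, with boundaries resolved by rounding at
#' voxel centres.
#'
#' @inheritParams world_to_voxel
#' @return n x 3 integer matrix of 0-based voxel indices.
#' @export
containing_voxel <- function(pts, affine) {
  v <- world_to_voxel(pts, affine)
  storage.mode(v) <- "double"
  round(v)
}

# coerce a vector or matrix to an n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  x
}

# TRUE for rows of 0-based ijk that fall inside a grid of dimension `dm`
in_grid <- function(ijk, dm) {
  ijk[, 1] >= 0 & ijk[, 1] <= dm[1] - 1 &
    ijk[, 2] >= 0 & ijk[, 2] <= dm[2] - 1 &
    ijk[, 3] >= 0 & ijk[, 3] <= dm[3] - 1
}

# 1-based linear index into a 3-D array from 0-based ijk rows
linear_index <- function(ijk, dm) {
  1L + ijk[, 1] + dm[1] * (ijk[, 2] + dm[2] * ijk[, 3])
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream-specific child seed from a base seed (kept below 2^31)
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}
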
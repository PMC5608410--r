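# Synthetic eigen-field fixtures for tractography tests.

# straight x-aligned bundle (radius 2 voxels) in an isotropic background
straight_bundle_field <- function(dm = c(26L, 20L, 20L), len_vox = 20L) {
  dirs <- array(0, c(dm, 3L))
  dirs[, , , 1] <- 1
  inside <- array(FALSE, dm)
  x0 <- (dm[1] - len_vox) %/% 2 + 1
  xs <- x0:(x0 + len_vox - 1)
  ctr <- (dm[2:3] + 1) / 2
  for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if ((j - ctr[1])^2 + (k - ctr[2])^2 <= 4) inside[xs, j, k] <- TRUE
  }
  tf <- make_tensor_field_from_dirs(dirs, inside)
  ef <- eigendecompose(tf)
  list(ef = ef, fa = scalar_maps(ef)$fa, inside = inside, xs = xs)
}

# slab with an abrupt 60-degree fibre-direction change at x = xc (0-based)
kink_field <- function(dm = c(16L, 20L, 5L), xc = 8L) {
  dirs <- array(0, c(dm, 3L))
  for (i in seq_len(dm[1])) {
    d <- if (i - 1 < xc) c(1, 0, 0) else c(cos(pi / 3), sin(pi / 3), 0)
    dirs[i, , , 1] <- d[1]; dirs[i, , , 2] <- d[2]; dirs[i, , , 3] <- d[3]
  }
  inside <- array(FALSE, dm)
  inside[, , 2:4] <- TRUE
  tf <- make_tensor_field_from_dirs(dirs, inside)
  ef <- eigendecompose(tf)
  list(ef = ef, fa = scalar_maps(ef)$fa, xc = xc)
}

# largest per-step turning angle (degrees) along a streamline
max_step_turn_deg <- function(line) {
  if (nrow(line) < 3) return(0)
  d <- diff(line)
  d <- d / sqrt(rowSums(d^2))
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  max(acos(pmin(pmax(dots, -1), 1)) * 180 / pi)
}
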
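# Deterministic streamline tractography over the principal eigenvector
# field (FACT-style), with fixed-step Euler integration, bidirectional
# propagation from every suprathreshold voxel, and the classical FA and
# turning-angle stopping rules.

#' Tracking parameters
#'
#' @param fa_threshold Minimum FA for seeding and propagation (default 0.2).
#' @param angle_threshold Maximum turn between consecutive steps, degrees
#'   (default 30).
#' @param step_size Euler step, mm (default 1, i.e. half a 2 mm voxel).
#' @param min_length Minimum streamline length, mm (default 10).
#' @param max_length Maximum half-track length, mm (default 250).
#' @param seeds_per_voxel Seeds per suprathreshold voxel (default 1, at the
#'   voxel centre; additional seeds are jittered uniformly inside the
#'   voxel).
#' @param interpolation `"nearest"` (default) takes the principal direction
#'   of the voxel containing the current point, as in fibre assignment by
#'   continuous tracking; `"trilinear"` interpolates the six tensor
#'   components trilinearly and re-extracts the principal eigenvector.
#' @param seed RNG seed (only used when `seeds_per_voxel > 1`).
#' @return A `tracking_params` object.
#' @export
tracking_params <- function(fa_threshold = 0.2, angle_threshold = 30,
                            step_size = 1, min_length = 10, max_length = 250,
                            seeds_per_voxel = 1L,
                            interpolation = c("nearest", "trilinear"),
                            seed = 1L) {
  interpolation <- match.arg(interpolation)
  stopifnot(fa_threshold > 0, fa_threshold < 1,
            angle_threshold > 0, angle_threshold < 90,
            step_size > 0, min_length >= 0, max_length > 0,
            seeds_per_voxel >= 1L)
  structure(list(fa_threshold = fa_threshold, angle_threshold = angle_threshold,
                 step_size = step_size, min_length = min_length,
                 max_length = max_length,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 interpolation = interpolation, seed = seed),
            class = "tracking_params")
}

#' A set of streamlines
#'
#' @param streamlines List of n x 3 matrices of ordered points in world mm.
#' @param voxel_size Voxel size of the source grid, mm.
#' @param affine Voxel-to-world affine of the source grid.
#' @param dim Grid dimensions.
#' @return A `streamline_set` object.
#' @export
streamline_set <- function(streamlines, voxel_size, affine, dim) {
  structure(list(streamlines = streamlines,
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 affine = affine, dim = as.integer(dim)),
            class = "streamline_set")
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' @export
print.streamline_set <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("streamline_set: %d streamlines (%d points total) on a %s grid\n",
              length(x$streamlines), sum(npts),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# direction lookup closure for a given eigen field and interpolation mode
make_direction_fn <- function(ef, interpolation) {
  dm <- dim(ef$valid_mask)
  if (interpolation == "nearest") {
    pd <- ef$principal_direction
    function(ijk_frac) {
      ijk <- round(ijk_frac)
      pd[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L, ]
    }
  } else {
    tens <- ef$tensor
    function(ijk_frac) {
      f0 <- floor(ijk_frac)
      f0 <- pmin(pmax(f0, 0), dm - 2)
      w <- ijk_frac - f0
      D6 <- numeric(6)
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
        if (wt > 0) {
          D6 <- D6 + wt * tens[f0[1] + dx + 1L, f0[2] + dy + 1L,
                               f0[3] + dz + 1L, ]
        }
      }
      D <- matrix(c(D6[1], D6[4], D6[5],
                    D6[4], D6[2], D6[6],
                    D6[5], D6[6], D6[3]), 3, 3)
      eigen(D, symmetric = TRUE)$vectors[, 1]
    }
  }
}

#' Whole-brain deterministic tractography
#'
#' Seeds are placed in every voxel whose FA meets `fa_threshold`.
#' Integration is bidirectional from each seed by fixed-step Euler along
#' the principal diffusion direction, with step-to-step sign alignment.
#' Propagation stops when the containing voxel leaves the volume or its FA
#' drops below threshold, when the turn between consecutive steps exceeds
#' the angle threshold, or at the maximum length. The two half-tracks are
#' concatenated and streamlines shorter than `min_length` are discarded.
#'
#' @param ef An `eigen_field` from [eigendecompose()].
#' @param fa The FA [scalar_volume()] on the same grid.
#' @param params A [tracking_params()].
#' @return A [streamline_set()] (possibly empty; an empty suprathreshold
#'   set is not an error).
#' @export
track_whole_brain <- function(ef, fa, params = tracking_params()) {
  stopifnot(inherits(ef, "eigen_field"), inherits(fa, "scalar_volume"),
            inherits(params, "tracking_params"))
  dm <- dim(fa$values)
  stopifnot(identical(dm, dim(ef$valid_mask)))
  vox <- ef$voxel_size
  A <- ef$affine

  fa_ok <- is.finite(fa$values) & (fa$values >= params$fa_threshold) &
    ef$valid_mask
  seeds <- which(fa_ok, arr.ind = TRUE) - 1L  # 0-based
  if (nrow(seeds) == 0L) {
    return(streamline_set(list(), vox, A, dm))
  }

  seed_pts <- voxel_to_world(seeds, A)
  if (params$seeds_per_voxel > 1L) {
    extra <- with_seed(child_seed(params$seed, 3L), {
      lapply(seq_len(params$seeds_per_voxel - 1L), function(i) {
        jit <- matrix(stats::runif(nrow(seeds) * 3, -0.5, 0.5),
                      ncol = 3) %*% diag(vox)
        seed_pts + jit
      })
    })
    seed_pts <- do.call(rbind, c(list(seed_pts), extra))
  }

  dir_at <- make_direction_fn(ef, params$interpolation)
  cos_thr <- cos(params$angle_threshold * pi / 180)
  step <- params$step_size
  max_steps <- ceiling(params$max_length / step)
  Ainv <- solve(A)

  to_vox <- function(p) {
    (Ainv[1:3, 1:3] %*% p + Ainv[1:3, 4])[, 1]
  }

  half_track <- function(p0, d0) {
    pts <- matrix(NA_real_, max_steps + 1L, 3)
    pts[1L, ] <- p0
    n <- 1L
    d_prev <- d0
    pos <- p0
    repeat {
      vf <- to_vox(pos)
      d_new <- dir_at(vf)
      if (!all(is.finite(d_new))) break
      if (sum(d_new * d_prev) < 0) d_new <- -d_new
      # turning-angle stopping rule (between consecutive step directions)
      if (n > 1L && sum(d_new * d_prev) < cos_thr - 1e-12) break
      pos_new <- pos + step * d_new
      ijk <- round(to_vox(pos_new))
      if (any(ijk < 0) || any(ijk > dm - 1L)) break
      if (!fa_ok[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]) break
      n <- n + 1L
      pts[n, ] <- pos_new
      pos <- pos_new
      d_prev <- d_new
      if (n > max_steps) break
    }
    pts[seq_len(n), , drop = FALSE]
  }

  out <- vector("list", nrow(seed_pts))
  n_out <- 0L
  for (s in seq_len(nrow(seed_pts))) {
    p0 <- seed_pts[s, ]
    d0 <- dir_at(to_vox(p0))
    if (!all(is.finite(d0))) next
    fwd <- half_track(p0, d0)
    bwd <- half_track(p0, -d0)
    if (nrow(bwd) > 1L) {
      line <- rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE],
                    fwd)
    } else {
      line <- fwd
    }
    if (nrow(line) < 2L) next
    if ((nrow(line) - 1L) * step < params$min_length) next
    n_out <- n_out + 1L
    out[[n_out]] <- line
  }
  streamline_set(out[seq_len(n_out)], vox, A, dm)
}
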
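# Atlas-style tract segmentation: an AND-ROI the streamline must touch and
# a shell-shaped NOT-ROI (dilation minus tract) it must avoid, followed by
# per-tract averaging of MD/FA over the visited voxels.

#' Binary morphological dilation of a 3-D mask
#'
#' @param mask 3-D logical array.
#' @param radius Number of dilation iterations (voxels).
#' @param metric `"chebyshev"` (default) applies 26-connected dilation
#'   `radius` times, growing a Chebyshev ball; `"euclidean"` dilates by a
#'   Euclidean ball of the given radius in one pass.
#' @return Dilated logical array of the same dimensions.
#' @export
dilate_mask <- function(mask, radius = 1L, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(length(dim(mask)) == 3L, radius >= 0)
  if (radius == 0 || !any(mask)) return(mask)
  dm <- dim(mask)
  shift3 <- function(m, dx, dy, dz) {
    out <- array(FALSE, dm)
    xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zs <- seq_len(dm[3])
    sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
    okx <- sx >= 1 & sx <= dm[1]
    oky <- sy >= 1 & sy <= dm[2]
    okz <- sz >= 1 & sz <= dm[3]
    out[xs[okx], ys[oky], zs[okz]] <- m[sx[okx], sy[oky], sz[okz]]
    out
  }
  if (metric == "chebyshev") {
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    out <- mask
    for (it in seq_len(radius)) {
      acc <- out
      for (r in seq_len(nrow(offs))) {
        o <- offs[r, ]
        if (all(o == 0)) next
        acc <- acc | shift3(out, o[1], o[2], o[3])
      }
      out <- acc
    }
  } else {
    r <- ceiling(radius)
    offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
    offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
    acc <- array(FALSE, dm)
    for (rr in seq_len(nrow(offs))) {
      o <- offs[rr, ]
      acc <- acc | shift3(mask, o[1], o[2], o[3])
    }
    out <- acc
  }
  out
}

#' Resample an atlas label into the subject grid (AND-ROI)
#'
#' Nearest-neighbour projection of a binary atlas label through an
#' invertible affine transform (identity in the fully synthetic setting).
#' For each subject voxel centre, the corresponding atlas voxel is looked
#' up through the inverse transform.
#'
#' @param atlas_mask 3-D logical array, the atlas label.
#' @param transform 4x4 affine mapping atlas world coordinates to subject
#'   world coordinates.
#' @param atlas_affine Voxel-to-world affine of the atlas grid.
#' @param subject_dim Dimensions of the subject grid (default: atlas grid).
#' @param subject_affine Voxel-to-world affine of the subject grid
#'   (default: `atlas_affine`).
#' @param name Tract name used in error messages.
#' @return 3-D logical mask on the subject grid.
#' @export
build_and_roi <- function(atlas_mask, transform = diag(4),
                          atlas_affine = vox_affine(c(2, 2, 2)),
                          subject_dim = dim(atlas_mask),
                          subject_affine = atlas_affine,
                          name = "tract") {
  stopifnot(length(dim(atlas_mask)) == 3L)
  if (abs(det(transform)) < 1e-12) stop("transform is not invertible")
  dm_s <- as.integer(subject_dim)
  dm_a <- dim(atlas_mask)
  ijk_s <- as.matrix(expand.grid(i = 0:(dm_s[1] - 1), j = 0:(dm_s[2] - 1),
                                 k = 0:(dm_s[3] - 1)))
  w_s <- voxel_to_world(ijk_s, subject_affine)
  w_a <- t(solve(transform)[1:3, ] %*% t(cbind(w_s, 1)))
  ijk_a <- containing_voxel(w_a, atlas_affine)
  ok <- in_grid(ijk_a, dm_a)
  vals <- logical(nrow(ijk_s))
  vals[ok] <- atlas_mask[linear_index(ijk_a[ok, , drop = FALSE], dm_a)]
  out <- array(vals, dm_s)
  if (!any(out)) {
    stop(sprintf("AND-ROI for tract '%s' is empty after resampling", name))
  }
  out
}

#' Build the shell-shaped NOT-ROI around a tract mask
#'
#' The tract mask is enlarged by `radius` voxels from its border and the
#' tract itself subtracted, leaving a shell of thickness `radius` that
#' surrounds the tract.
#'
#' @param tract_mask 3-D logical array.
#' @param radius Shell thickness in voxels (default 5).
#' @param metric Dilation metric, see [dilate_mask()].
#' @return 3-D logical shell mask, disjoint from `tract_mask`.
#' @export
build_not_shell <- function(tract_mask, radius = 5L,
                            metric = c("chebyshev", "euclidean")) {
  stopifnot(radius >= 1)
  metric <- match.arg(metric)
  dilate_mask(tract_mask, radius, metric) & !tract_mask
}

#' Define a tract by its AND-ROI and NOT-shell
#'
#' @param name Tract name.
#' @param and_roi 3-D logical inclusion mask.
#' @param not_shell Optional 3-D logical exclusion shell; built with
#'   [build_not_shell()] at `dilation_radius` when omitted.
#' @param dilation_radius Shell thickness in voxels (default 5).
#' @return A `tract_definition` object.
#' @export
tract_definition <- function(name, and_roi, not_shell = NULL,
                             dilation_radius = 5L) {
  if (is.null(not_shell)) {
    not_shell <- build_not_shell(and_roi, dilation_radius)
  }
  stopifnot(identical(dim(and_roi), dim(not_shell)))
  if (any(and_roi & not_shell)) {
    stop("and_roi and not_shell overlap")
  }
  structure(list(name = as.character(name), and_roi = and_roi,
                 not_shell = not_shell,
                 dilation_radius = as.integer(dilation_radius)),
            class = "tract_definition")
}

# 0-based voxel indices of every vertex of a streamline
streamline_voxels <- function(line, affine) {
  containing_voxel(line, affine)
}

#' Filter a streamline set by a tract definition
#'
#' Retains exactly the streamlines with at least one vertex inside the
#' AND-ROI and no vertex inside the NOT-shell. Vertices are assigned to
#' voxels by world-to-voxel rounding; vertices outside the grid count as
#' outside both masks.
#'
#' @param streams A [streamline_set()].
#' @param tdef A [tract_definition()] on the same grid.
#' @return A [streamline_set()] with the retained streamlines.
#' @export
segment_tract <- function(streams, tdef) {
  stopifnot(inherits(streams, "streamline_set"),
            inherits(tdef, "tract_definition"))
  dm <- dim(tdef$and_roi)
  stopifnot(identical(as.integer(dm), streams$dim))
  keep <- vapply(streams$streamlines, function(line) {
    ijk <- streamline_voxels(line, streams$affine)
    ok <- in_grid(ijk, dm)
    if (!any(ok)) return(FALSE)
    lin <- linear_index(ijk[ok, , drop = FALSE], dm)
    any(tdef$and_roi[lin]) && !any(tdef$not_shell[lin])
  }, logical(1))
  streamline_set(streams$streamlines[keep], streams$voxel_size,
                 streams$affine, streams$dim)
}

#' Per-tract summary of MD and FA
#'
#' The tract mean is computed over the set of unique voxels visited by any
#' retained streamline (each voxel counted once, regardless of how many
#' streamlines or vertices touch it).
#'
#' @param md,fa [scalar_volume()]s on the streamline grid.
#' @param segmented A non-empty [streamline_set()] (after
#'   [segment_tract()]).
#' @param name Tract name for the summary.
#' @return A `tract_summary`: list with `name`, `n_streamlines`,
#'   `n_voxels`, `mean_md`, `mean_fa`.
#' @export
tract_summary <- function(md, fa, segmented, name) {
  stopifnot(inherits(md, "scalar_volume"), inherits(fa, "scalar_volume"),
            inherits(segmented, "streamline_set"))
  if (length(segmented$streamlines) == 0L) {
    stop(sprintf("tract '%s' not reconstructed: no streamlines retained", name))
  }
  dm <- dim(md$values)
  lin_all <- unlist(lapply(segmented$streamlines, function(line) {
    ijk <- streamline_voxels(line, segmented$affine)
    ok <- in_grid(ijk, dm)
    linear_index(ijk[ok, , drop = FALSE], dm)
  }))
  vox <- unique(lin_all)
  structure(list(name = name,
                 n_streamlines = length(segmented$streamlines),
                 n_voxels = length(vox),
                 mean_md = mean(md$values[vox]),
                 mean_fa = mean(fa$values[vox])),
            class = "tract_summary")
}

#' QC report for a segmented tract
#'
#' Replaces manual tract editing with a transparent report: streamline and
#' voxel counts plus a visitation-count map.
#'
#' @inheritParams tract_summary
#' @return List with `name`, `n_streamlines`, `visitation` (3-D integer
#'   array of per-voxel streamline visit counts).
#' @export
tract_qc <- function(md, fa, segmented, name) {
  dm <- dim(md$values)
  visit <- array(0L, dm)
  for (line in segmented$streamlines) {
    ijk <- streamline_voxels(line, segmented$affine)
    ok <- in_grid(ijk, dm)
    lin <- unique(linear_index(ijk[ok, , drop = FALSE], dm))
    visit[lin] <- visit[lin] + 1L
  }
  list(name = name, n_streamlines = length(segmented$streamlines),
       visitation = visit)
}
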
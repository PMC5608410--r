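# Image-level diffusion phantoms: tract bundles with known tensor fields,
# a designated "ventricular" region, and WMH-like lesions with elevated MD
# and reduced FA placed preferentially near the ventricles.

#' Describe a tract bundle geometry for a phantom
#'
#' Bundles are tubes of circular cross-section, either straight (aligned
#' with a grid axis) or following a circular arc.
#'
#' @param name Tract name (used in masks and error messages).
#' @param shape `"straight"` or `"arc"`.
#' @param axis For straight bundles, the grid axis (1, 2 or 3) the bundle
#'   runs along.
#' @param center Length-3 numeric, bundle centre in mm relative to the grid
#'   centre.
#' @param length Bundle length in mm (straight bundles).
#' @param radius Tube cross-section radius in mm.
#' @param arc_radius Arc radius in mm (arc bundles).
#' @param arc_plane Length-2 integer, the two grid axes spanning the arc
#'   plane (arc bundles).
#' @param arc_span Length-2 numeric, start and end angle of the arc in
#'   radians (arc bundles).
#' @return A `tract_geometry` object.
#' @export
tract_geometry <- function(name, shape = c("straight", "arc"), axis = 1L,
                           center = c(0, 0, 0), length = 40, radius = 4,
                           arc_radius = 15, arc_plane = c(1L, 3L),
                           arc_span = c(0, pi)) {
  shape <- match.arg(shape)
  stopifnot(length > 0, radius > 0, arc_radius > 0,
            axis %in% 1:3, all(arc_plane %in% 1:3),
            arc_plane[1] != arc_plane[2], length(center) == 3)
  structure(list(name = as.character(name), shape = shape, axis = as.integer(axis),
                 center = as.numeric(center), length = length, radius = radius,
                 arc_radius = arc_radius, arc_plane = as.integer(arc_plane),
                 arc_span = as.numeric(arc_span)),
            class = "tract_geometry")
}

default_tract_geometries <- function() {
  list(
    tract_geometry("slf_analog", "straight", axis = 1L,
                   center = c(0, -12, 10), length = 56, radius = 4),
    tract_geometry("cst_analog", "straight", axis = 3L,
                   center = c(12, 14, 0), length = 56, radius = 4)
  )
}

#' Specify an image-level diffusion phantom
#'
#' Defaults follow a 2 mm isotropic acquisition on a 40^3 grid with two
#' straight bundles, cerebrospinal-fluid-like ventricles in the centre of
#' the volume, and lesion eigenvalues giving higher MD and lower FA than
#' normal-appearing white matter (validated at construction).
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size Voxel edge length(s) in mm.
#' @param tract_geometries List of [tract_geometry()] objects.
#' @param lesion_load_target Lesion volume as a fraction of the brain mask
#'   (in `[0, 1)`).
#' @param lesion_site_bias Decay length (in voxels) of the exponential
#'   placement weight `exp(-d / lesion_site_bias)`, where `d` is the
#'   Chebyshev distance to the ventricular region. Larger values spread
#'   lesions more uniformly.
#' @param lesion_within Optional character vector of tract names; when
#'   given, lesions are confined to those bundles.
#' @param nawm_eigenvalues Tensor eigenvalues (l1 >= l2 >= l3, um^2/ms)
#'   inside tract bundles.
#' @param background_eigenvalue Isotropic diffusivity (um^2/ms) of
#'   non-tract brain tissue.
#' @param csf_eigenvalue Isotropic diffusivity (um^2/ms) of the ventricular
#'   region.
#' @param lesion_eigenvalues Tensor eigenvalues (um^2/ms) inside lesions;
#'   must yield higher MD and lower FA than `nawm_eigenvalues`.
#' @param s0 Non-diffusion-weighted signal amplitude inside the brain.
#' @param snr_b0 Signal-to-noise ratio of the b=0 signal (`Inf` disables
#'   noise).
#' @param seed RNG seed for lesion placement and noise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L), voxel_size = 2,
                         tract_geometries = default_tract_geometries(),
                         lesion_load_target = 0, lesion_site_bias = 4,
                         lesion_within = NULL,
                         nawm_eigenvalues = c(1.4, 0.45, 0.45),
                         background_eigenvalue = 0.8,
                         csf_eigenvalue = 3.0,
                         lesion_eigenvalues = c(1.6, 1.0, 0.85),
                         s0 = 500, snr_b0 = 30, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(grid_shape >= 8L), all(voxel_size > 0),
            lesion_load_target >= 0, lesion_load_target < 1,
            lesion_site_bias > 0, s0 > 0, snr_b0 > 0,
            length(nawm_eigenvalues) == 3, length(lesion_eigenvalues) == 3,
            all(nawm_eigenvalues > 0), all(lesion_eigenvalues > 0))
  if (md_from_eigenvalues(lesion_eigenvalues[1], lesion_eigenvalues[2],
                          lesion_eigenvalues[3]) <=
      md_from_eigenvalues(nawm_eigenvalues[1], nawm_eigenvalues[2],
                          nawm_eigenvalues[3])) {
    stop("lesion eigenvalues must yield higher MD than NAWM eigenvalues")
  }
  if (fa_from_eigenvalues(lesion_eigenvalues[1], lesion_eigenvalues[2],
                          lesion_eigenvalues[3]) >=
      fa_from_eigenvalues(nawm_eigenvalues[1], nawm_eigenvalues[2],
                          nawm_eigenvalues[3])) {
    stop("lesion eigenvalues must yield lower FA than NAWM eigenvalues")
  }
  if (is.list(tract_geometries) && inherits(tract_geometries, "tract_geometry")) {
    tract_geometries <- list(tract_geometries)
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 tract_geometries = tract_geometries,
                 lesion_load_target = lesion_load_target,
                 lesion_site_bias = lesion_site_bias,
                 lesion_within = lesion_within,
                 nawm_eigenvalues = as.numeric(nawm_eigenvalues),
                 background_eigenvalue = background_eigenvalue,
                 csf_eigenvalue = csf_eigenvalue,
                 lesion_eigenvalues = as.numeric(lesion_eigenvalues),
                 s0 = s0, snr_b0 = snr_b0, seed = seed),
            class = "phantom_spec")
}

# world-mm coordinates (relative to grid centre) of every voxel centre
voxel_center_grid <- function(dm, voxel_size) {
  ctr <- (dm - 1) / 2 * voxel_size
  i <- (seq_len(dm[1]) - 1) * voxel_size[1] - ctr[1]
  j <- (seq_len(dm[2]) - 1) * voxel_size[2] - ctr[2]
  k <- (seq_len(dm[3]) - 1) * voxel_size[3] - ctr[3]
  list(x = array(rep(i, times = dm[2] * dm[3]), dm),
       y = array(rep(rep(j, each = dm[1]), times = dm[3]), dm),
       z = array(rep(k, each = dm[1] * dm[2]), dm))
}

# membership mask and per-voxel unit fibre direction for one bundle
tract_voxels <- function(geom, W, dm) {
  ax <- list(W$x, W$y, W$z)
  if (geom$shape == "straight") {
    a <- geom$axis
    perp <- setdiff(1:3, a)
    along <- ax[[a]] - geom$center[a]
    d2 <- (ax[[perp[1]]] - geom$center[perp[1]])^2 +
      (ax[[perp[2]]] - geom$center[perp[2]])^2
    mask <- abs(along) <= geom$length / 2 & d2 <= geom$radius^2
    dir <- matrix(0, sum(mask), 3)
    dir[, a] <- 1
  } else {
    p <- geom$arc_plane[1]; q <- geom$arc_plane[2]
    o <- setdiff(1:3, geom$arc_plane)
    rp <- ax[[p]] - geom$center[p]
    rq <- ax[[q]] - geom$center[q]
    ro <- ax[[o]] - geom$center[o]
    rin <- sqrt(rp^2 + rq^2)
    theta <- atan2(rq, rp)
    span <- sort(geom$arc_span)
    d2 <- (rin - geom$arc_radius)^2 + ro^2
    mask <- d2 <= geom$radius^2 & theta >= span[1] & theta <= span[2]
    th <- theta[mask]
    dir <- matrix(0, sum(mask), 3)
    dir[, p] <- -sin(th)
    dir[, q] <- cos(th)
  }
  list(mask = mask, dir = dir)
}

# Chebyshev distance (in voxels) from `target` within the full grid,
# computed by breadth-first 26-connected dilation layers.
chebyshev_distance_map <- function(target, max_dist = NULL) {
  dm <- dim(target)
  if (is.null(max_dist)) max_dist <- sum(dm)
  d <- array(Inf, dm)
  d[target] <- 0
  frontier <- target
  visited <- target
  k <- 0
  while (any(frontier) && k < max_dist) {
    k <- k + 1
    frontier <- dilate_mask(frontier, 1L) & !visited
    d[frontier] <- k
    visited <- visited | frontier
    if (all(visited)) break
  }
  d
}

#' Build an image-level phantom with known tensor field
#'
#' Constructs the brain, ventricle, tract and lesion masks and the
#' ground-truth per-voxel tensor implied by a [phantom_spec()]. Lesion
#' voxels carry the lesion eigenvalues (in the local fibre frame), are
#' confined to the brain mask, and are placed by sampling blob centres with
#' probability proportional to `exp(-d / lesion_site_bias)` of the Chebyshev
#' distance `d` to the ventricular region. The achieved lesion voxel count
#' equals `round(lesion_load_target * brain voxels)` exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `truth` (a `tensor_field` holding the
#'   ground-truth tensor and s0), `truth_eigenvalues` (x,y,z,3 array),
#'   `truth_md`, `truth_fa`, `brain_mask`, `ventricle_mask`, `lesion_mask`,
#'   `tract_masks` (named list), `voxel_size`, `affine` and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  vox <- spec$voxel_size
  W <- voxel_center_grid(dm, vox)
  half <- (dm - 1) / 2 * vox

  # brain: centred ellipsoid at 90% of the half-extent
  semi <- 0.9 * half
  brain <- (W$x / semi[1])^2 + (W$y / semi[2])^2 + (W$z / semi[3])^2 <= 1

  # ventricular region: centred box
  vent_half <- c(10, 6, 6)
  vent <- abs(W$x) <= vent_half[1] & abs(W$y) <= vent_half[2] &
    abs(W$z) <= vent_half[3]

  # per-voxel eigenvalues and principal direction, background first
  nvox <- prod(dm)
  ev <- matrix(spec$background_eigenvalue, nvox, 3)
  e1 <- matrix(rep(c(1, 0, 0), each = nvox), nvox, 3)
  ev[vent, ] <- spec$csf_eigenvalue

  tract_masks <- list()
  for (geom in spec$tract_geometries) {
    tv <- tract_voxels(geom, W, dm)
    if (!any(tv$mask)) {
      stop(sprintf("tract '%s' produced an empty mask", geom$name))
    }
    # the geometry must fit the grid: its analytic extent may not touch the
    # boundary layer
    idx <- which(tv$mask, arr.ind = TRUE)
    if (any(idx == 1L) || any(sweep(idx, 2, dm, "=="))) {
      stop(sprintf("tract '%s' exceeds the phantom grid", geom$name))
    }
    tract_masks[[geom$name]] <- tv$mask
    ev[tv$mask, ] <- matrix(spec$nawm_eigenvalues, sum(tv$mask), 3, byrow = TRUE)
    e1[tv$mask, ] <- tv$dir
  }

  # brain holds everything we simulate signal for
  any_tract <- Reduce(`|`, tract_masks, array(FALSE, dm))
  brain <- brain | vent | any_tract

  # lesions
  lesion <- array(FALSE, dm)
  n_target <- round(spec$lesion_load_target * sum(brain))
  if (n_target > 0) {
    cand <- brain
    if (!is.null(spec$lesion_within)) {
      missing <- setdiff(spec$lesion_within, names(tract_masks))
      if (length(missing)) {
        stop("lesion_within names unknown tracts: ", paste(missing, collapse = ", "))
      }
      cand <- Reduce(`|`, tract_masks[spec$lesion_within], array(FALSE, dm))
    }
    if (sum(cand) < n_target) {
      stop("lesion_load_target exceeds the available candidate volume")
    }
    dmap <- chebyshev_distance_map(vent)
    wgt <- exp(-dmap / spec$lesion_site_bias)
    lesion <- with_seed(child_seed(spec$seed, 1L), {
      place_lesions(cand, wgt, n_target, dm)
    })
    # lesion voxels keep the local fibre frame but take lesion eigenvalues
    ev[lesion, ] <- matrix(spec$lesion_eigenvalues, sum(lesion), 3, byrow = TRUE)
  }

  # per-voxel tensors: voxels share one of a handful of eigenvalue triples,
  # but directions vary, so build from (e1, ev) row-wise
  tensor <- build_tensor_rows(e1, ev)
  tensor[!brain, ] <- 0

  s0 <- array(0, dm)
  s0[brain] <- spec$s0

  l1 <- array(ev[, 1], dm); l2 <- array(ev[, 2], dm); l3 <- array(ev[, 3], dm)
  truth_md <- md_from_eigenvalues(l1, l2, l3)
  truth_fa <- fa_from_eigenvalues(l1, l2, l3)
  truth_md[!brain] <- 0
  truth_fa[!brain] <- 0

  truth <- tensor_field(array(tensor, c(dm, 6L)), s0, brain, vox)

  list(truth = truth,
       truth_eigenvalues = array(ev, c(dm, 3L)),
       truth_md = truth_md, truth_fa = truth_fa,
       brain_mask = brain, ventricle_mask = vent, lesion_mask = lesion,
       tract_masks = tract_masks,
       voxel_size = vox, affine = vox_affine(vox), spec = spec)
}

# row-wise D = sum_m ev[,m] * e_m e_m^T with e1 given and (e2,e3) an
# orthonormal completion; vectorised over voxels
build_tensor_rows <- function(e1, ev) {
  n <- nrow(e1)
  ref <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  swap <- abs(e1[, 3]) > 0.9
  if (any(swap)) ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  e2 <- cross(e1, ref)
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cross(e1, e2)
  D <- matrix(0, n, 6)
  basis <- list(e1, e2, e3)
  for (m in 1:3) {
    e <- basis[[m]]
    l <- ev[, m]
    D[, 1] <- D[, 1] + l * e[, 1]^2
    D[, 2] <- D[, 2] + l * e[, 2]^2
    D[, 3] <- D[, 3] + l * e[, 3]^2
    D[, 4] <- D[, 4] + l * e[, 1] * e[, 2]
    D[, 5] <- D[, 5] + l * e[, 1] * e[, 3]
    D[, 6] <- D[, 6] + l * e[, 2] * e[, 3]
  }
  D
}

# grow lesion blobs until exactly n_target voxels are lesioned
place_lesions <- function(cand, wgt, n_target, dm) {
  lesion <- array(FALSE, dm)
  offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  offs_r2 <- rowSums(offs^2)
  n_placed <- 0L
  last_added <- integer(0)
  guard <- 0L
  while (n_placed < n_target) {
    guard <- guard + 1L
    if (guard > 10L * n_target) stop("lesion placement failed to converge")
    open <- which(cand & !lesion)
    if (!length(open)) stop("lesion placement ran out of candidate voxels")
    ctr <- open[sample.int(length(open), 1L, prob = wgt[open])]
    r <- sample(1:2, 1L)
    cij <- arrayInd(ctr, dm)
    ball <- offs[offs_r2 <= r^2, , drop = FALSE]
    pts <- sweep(ball, 2, cij, `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
      pts[, 2] >= 1 & pts[, 2] <= dm[2] &
      pts[, 3] >= 1 & pts[, 3] <= dm[3]
    pts <- pts[ok, , drop = FALSE]
    lin <- pts[, 1] + dm[1] * (pts[, 2] - 1) + dm[1] * dm[2] * (pts[, 3] - 1)
    lin <- lin[cand[lin] & !lesion[lin]]
    if (!length(lin)) next
    lesion[lin] <- TRUE
    last_added <- lin
    n_placed <- n_placed + length(lin)
  }
  if (n_placed > n_target) {
    drop_n <- n_placed - n_target
    drop <- sample(last_added, drop_n)
    lesion[drop] <- FALSE
  }
  lesion
}
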
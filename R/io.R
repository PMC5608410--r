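# Standard-format I/O: NIfTI volumes via RNifti, FSL-style bvals/bvecs,
# TrackVis .trk streamline files (with a JSON-lines fallback), TSV cohort
# tables and YAML parameter sidecars.

as_nifti_vol <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, rep_len(voxel_size, 3L))
  img
}

#' Write a volume (3-D or 4-D array) as NIfTI
#'
#' @param arr Numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size in mm.
#' @param datatype NIfTI datatype (default `"float"`; use `"uint8"` for
#'   masks).
#' @return The path, invisibly.
#' @export
write_volume <- function(arr, path, voxel_size = c(2, 2, 2),
                         datatype = "float") {
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- as_nifti_vol(arr, voxel_size)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume as a plain array with voxel size
#'
#' @param path NIfTI file path.
#' @return List with `data` (array), `voxel_size` (mm), `affine` (the
#'   diagonal voxel-to-world affine implied by the voxel size).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  list(data = as.array(img), voxel_size = vs, affine = vox_affine(vs))
}

#' Read a NIfTI mask as a logical array
#' @param path NIfTI file path.
#' @return List as in [read_volume()] with logical `data`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  v$data <- v$data > 0
  v
}

#' Write FSL-style bvals/bvecs text files
#'
#' `bvals` is one space-separated row; `bvecs` has three rows (x, y, z),
#' one column per volume. b-values are written in s/mm^2 (internal
#' ms/um^2 times 1000).
#'
#' @param bvals Numeric vector, ms/um^2.
#' @param bvecs n x 3 matrix.
#' @param bvals_path,bvecs_path Output paths.
#' @return `bvals_path`, invisibly.
#' @export
write_bvals_bvecs <- function(bvals, bvecs, bvals_path, bvecs_path) {
  writeLines(paste(format(bvals * 1000, trim = TRUE, digits = 17),
                   collapse = " "), bvals_path)
  tv <- t(rbind3(bvecs))
  writeLines(apply(tv, 1, function(r) paste(format(r, trim = TRUE,
                                                   digits = 17),
                                            collapse = " ")),
             bvecs_path)
  invisible(bvals_path)
}

#' Read FSL-style bvals/bvecs text files
#'
#' @param bvals_path,bvecs_path Input paths.
#' @return List with `bvals` (converted to ms/um^2) and `bvecs` (n x 3).
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE) / 1000
  bv <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(bv) == 3L) bv <- t(bv)
  dimnames(bv) <- NULL
  list(bvals = bvals, bvecs = bv)
}

#' Read a DWI acquisition from NIfTI + bvals/bvecs
#'
#' @param nifti_path 4-D NIfTI path.
#' @param bvals_path,bvecs_path FSL-style text files.
#' @return A [diffusion_acquisition()].
#' @export
read_dwi <- function(nifti_path, bvals_path, bvecs_path) {
  v <- read_volume(nifti_path)
  g <- read_bvals_bvecs(bvals_path, bvecs_path)
  diffusion_acquisition(v$data, g$bvals, g$bvecs, v$voxel_size)
}

#' Write a DWI acquisition to NIfTI + bvals/bvecs
#'
#' @param acq A [diffusion_acquisition()].
#' @param prefix Output prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @return The NIfTI path, invisibly.
#' @export
write_dwi <- function(acq, prefix) {
  nii <- paste0(prefix, ".nii.gz")
  write_volume(acq$signal, nii, acq$voxel_size)
  write_bvals_bvecs(acq$bvals, acq$bvecs,
                    paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(nii)
}

# ---- TrackVis .trk ---------------------------------------------------------
# Binary format, version 2: 1000-byte header followed by, per streamline,
# an int32 point count and the points as float32 triples in "voxmm"
# coordinates (voxel index times voxel size).

#' Write streamlines to a TrackVis .trk file
#'
#' @param streams A [streamline_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_streamlines_trk <- function(streams, path) {
  stopifnot(inherits(streams, "streamline_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(streams$dim), con, size = 2)             # dim
  writeBin(as.numeric(streams$voxel_size), con, size = 4)      # voxel_size
  writeBin(rep(0, 3), con, size = 4)                           # origin
  writeBin(0L, con, size = 2)                                  # n_scalars
  writeBin(raw(200), con)                                      # scalar names
  writeBin(0L, con, size = 2)                                  # n_properties
  writeBin(raw(200), con)                                      # property names
  A <- streams$affine
  writeBin(as.numeric(t(A)), con, size = 4)                    # vox_to_ras
  writeBin(raw(444), con)                                      # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL)                # voxel_order
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                        # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)                 # img orientation
  writeBin(raw(2), con)                                        # pad1
  writeBin(raw(6), con)                                        # invert/swap flags
  writeBin(length(streams$streamlines), con, size = 4)         # n_count
  writeBin(2L, con, size = 4)                                  # version
  writeBin(1000L, con, size = 4)                               # hdr_size
  Ainv <- solve(streams$affine)
  vs <- streams$voxel_size
  for (line in streams$streamlines) {
    # world -> voxel -> voxmm
    v <- t(Ainv[1:3, 1:3] %*% t(line) + Ainv[1:3, 4])
    vm <- sweep(v, 2, vs, "*")
    writeBin(nrow(line), con, size = 4)
    writeBin(as.numeric(t(vm)), con, size = 4)
  }
  invisible(path)
}

#' Read streamlines from a TrackVis .trk file
#'
#' @param path Input path.
#' @return A [streamline_set()] in world mm coordinates.
#' @export
read_streamlines_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 5))
  if (!identical(magic, "TRACK")) stop("not a TrackVis .trk file: ", path)
  readBin(con, raw(), 1)
  dm <- readBin(con, integer(), 3, size = 2)
  vs <- readBin(con, numeric(), 3, size = 4)
  readBin(con, numeric(), 3, size = 4)
  n_scalars <- readBin(con, integer(), 1, size = 2)
  readBin(con, raw(), 200)
  n_props <- readBin(con, integer(), 1, size = 2)
  readBin(con, raw(), 200)
  A <- matrix(readBin(con, numeric(), 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, raw(), 444)
  readBin(con, raw(), 4)  # voxel_order
  readBin(con, raw(), 4)  # pad2
  readBin(con, numeric(), 6, size = 4)
  readBin(con, raw(), 2)
  readBin(con, raw(), 6)
  n_count <- readBin(con, integer(), 1, size = 4)
  version <- readBin(con, integer(), 1, size = 4)
  hdr_size <- readBin(con, integer(), 1, size = 4)
  if (hdr_size != 1000L) stop("unexpected .trk header size: ", hdr_size)
  if (all(A == 0)) A <- vox_affine(vs)
  lines <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    np <- readBin(con, integer(), 1, size = 4)
    if (length(np) == 0L) break
    pts <- matrix(readBin(con, numeric(), 3 * np * (1L + n_scalars), size = 4),
                  ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) readBin(con, numeric(), n_props, size = 4)
    # voxmm -> voxel -> world
    v <- sweep(pts, 2, vs, "/")
    w <- t(A[1:3, 1:3] %*% t(v) + A[1:3, 4])
    i <- i + 1L
    lines[[i]] <- w
  }
  streamline_set(lines[seq_len(i)], vs, A, dm)
}

#' Write streamlines as JSON lines (plain-text fallback)
#'
#' One JSON object per line with the streamline's points (world mm); the
#' first line is a header object with the grid geometry.
#'
#' @param streams A [streamline_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_streamlines_jsonl <- function(streams, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(type = "header", dim = streams$dim,
                               voxel_size = streams$voxel_size),
                          auto_unbox = FALSE, digits = NA)
  writeLines(hdr, con)
  for (line in streams$streamlines) {
    writeLines(jsonlite::toJSON(list(type = "streamline",
                                     points = unname(line)), digits = NA), con)
  }
  invisible(path)
}

#' Read streamlines from a JSON-lines file
#' @param path Input path.
#' @return A [streamline_set()].
#' @export
read_streamlines_jsonl <- function(path) {
  txt <- readLines(path)
  hdr <- jsonlite::fromJSON(txt[1])
  lines <- lapply(txt[-1], function(l) {
    o <- jsonlite::fromJSON(l)
    matrix(o$points, ncol = 3)
  })
  streamline_set(lines, hdr$voxel_size, vox_affine(hdr$voxel_size),
                 as.integer(hdr$dim))
}

#' Write a cohort table as TSV
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV
#' @param path Input path.
#' @return A `cohort_table` data frame.
#' @export
read_cohort_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Echo generation parameters to a YAML sidecar
#'
#' @param params Named list of parameters (specs are flattened).
#' @param path Output `.yaml` path.
#' @return The path, invisibly.
#' @export
write_yaml_sidecar <- function(params, path) {
  flat <- rapply(params, function(x) {
    if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
    x
  }, how = "replace")
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Write a phantom (truth tensors, masks, parameters) to a directory
#'
#' @param phantom Result of [make_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$voxel_size
  write_volume(phantom$truth$tensor, file.path(dir, "truth_tensor.nii.gz"), vs)
  write_volume(phantom$truth_md, file.path(dir, "truth_md.nii.gz"), vs)
  write_volume(phantom$truth_fa, file.path(dir, "truth_fa.nii.gz"), vs)
  write_volume(phantom$brain_mask, file.path(dir, "brain_mask.nii.gz"), vs,
               datatype = "uint8")
  write_volume(phantom$ventricle_mask, file.path(dir, "ventricle_mask.nii.gz"),
               vs, datatype = "uint8")
  write_volume(phantom$lesion_mask, file.path(dir, "lesion_mask.nii.gz"), vs,
               datatype = "uint8")
  for (nm in names(phantom$tract_masks)) {
    write_volume(phantom$tract_masks[[nm]],
                 file.path(dir, sprintf("tract_%s.nii.gz", nm)), vs,
                 datatype = "uint8")
  }
  sp <- phantom$spec
  sp$tract_geometries <- lapply(sp$tract_geometries, unclass)
  write_yaml_sidecar(unclass(sp), file.path(dir, "phantom.yaml"))
  invisible(dir)
}
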
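# WMH-load and ventricle-volume quantification relative to intracranial
# volume, and the load-based subgroup classification.

#' Volume of a binary mask in millilitres
#'
#' Voxel count times voxel volume (mm^3), converted to ml.
#'
#' @param mask 3-D logical array.
#' @param voxel_size Voxel edge length(s), mm.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask, voxel_size) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  sum(mask) * prod(voxel_size) / 1000
}

#' Express a volume as a percentage of intracranial volume
#'
#' @param volume_ml Volume in ml (WMH or ventricles).
#' @param icv_ml Intracranial volume in ml; must be positive.
#' @return `100 * volume_ml / icv_ml`.
#' @export
percent_of_icv <- function(volume_ml, icv_ml) {
  if (any(icv_ml <= 0)) stop("intracranial volume must be positive")
  100 * volume_ml / icv_ml
}

#' Classify WMH load into lower / intermediate / higher
#'
#' Lower load is a WMH volume of at most 0.5% of the intracranial volume,
#' higher load at least 1%; both thresholds are inclusive. Subjects in
#' between are intermediate and excluded from the matched-subgroup
#' contrast.
#'
#' @param wmh_pct WMH volume as percent of ICV (non-negative).
#' @param lower Upper bound of the lower-load class, percent (default 0.5).
#' @param higher Lower bound of the higher-load class, percent (default 1).
#' @return Character vector in `{"lower", "intermediate", "higher"}`.
#' @export
classify_wmh_load <- function(wmh_pct, lower = 0.5, higher = 1.0) {
  if (any(wmh_pct < 0)) stop("WMH load cannot be negative")
  stopifnot(lower < higher)
  out <- rep("intermediate", length(wmh_pct))
  out[wmh_pct <= lower] <- "lower"
  out[wmh_pct >= higher] <- "higher"
  out
}
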
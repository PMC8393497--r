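#' Tumor-to-normal ratio map from a PET activity volume
#'
#' Divides every voxel's activity by the mean activity inside the
#' normal-reference mask (typically contralateral normal brain). The mean
#' (not peak) reference is used.
#'
#' @param pet `voxel_volume` with units `"activity"`.
#' @param reference_mask `mask_volume` on the same grid, non-empty.
#' @return `voxel_volume` with units `"ratio"`.
#' @export
compute_tn_map <- function(pet, reference_mask) {
  check_units(pet, "activity")
  check_same_grid(pet, reference_mask, "PET and reference mask")
  if (!any(reference_mask$data))
    stop_relaxo("empty-mask", "reference mask has no voxels")
  ref_mean <- mean(pet$data[reference_mask$data], na.rm = TRUE)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop_relaxo("bad-reference", "mean reference activity is ", ref_mean,
                "; must be > 0")
  voxel_volume(pet$data / ref_mean, pet$affine, "ratio")
}

#' Partition analysis-mask voxels by tumor-to-normal ratio
#'
#' Voxels with T/N strictly greater than the cutoff form the high-uptake
#' class; voxels at or below the cutoff (ties included) form the low-uptake
#' class. The two classes are exhaustive and exclusive over the analysis
#' mask.
#'
#' @param tn `voxel_volume` with units `"ratio"`.
#' @param analysis_mask `mask_volume` on the same grid (e.g. the
#'   FLAIR-hyperintense region).
#' @param cutoff T/N threshold (default 1.5).
#' @return a `tn_partition`: list with `tn_volume`, `high_mask`, `low_mask`,
#'   `n_high`, `n_low`, `cutoff`.
#' @export
partition_by_tn <- function(tn, analysis_mask, cutoff = 1.5) {
  check_units(tn, "ratio")
  check_same_grid(tn, analysis_mask, "T/N map and analysis mask")
  if (!any(analysis_mask$data))
    stop_relaxo("empty-mask", "analysis mask has no voxels")
  m <- analysis_mask$data
  high <- m & tn$data > cutoff
  low <- m & !high
  stopifnot(!any(high & low), all((high | low) == m))
  structure(list(
    tn_volume = tn,
    high_mask = mask_volume(high, tn$affine),
    low_mask = mask_volume(low, tn$affine),
    n_high = sum(high),
    n_low = sum(low),
    cutoff = cutoff
  ), class = "tn_partition")
}

#' @export
print.tn_partition <- function(x, ...) {
  cat("<tn_partition> cutoff ", x$cutoff, ": ", x$n_high, " high, ",
      x$n_low, " low voxels\n", sep = "")
  invisible(x)
}
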
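## WMH penumbra construction and partition of white matter into
## {baseline WMH, penumbra-stable, penumbra-progressing, NAWM, excluded}.

#' Penumbra construction parameters
#'
#' @param radius_mm dilation radius in mm (default 3: new lesion growth
#'   concentrates within 3 mm of the existing WMH edge).
#' @param connectivity neighbour rule used for cluster/component work
#'   downstream (6, 18 or 26).
#' @return object of class `penumbra_config`.
#' @export
penumbra_config <- function(radius_mm = 3, connectivity = 26) {
  if (radius_mm <= 0) stop("radius_mm must be positive")
  structure(list(radius_mm = radius_mm, connectivity = connectivity),
            class = "penumbra_config")
}

check_same_grid <- function(...) {
  dims <- lapply(list(...), dim)
  dims <- dims[!vapply(dims, is.null, TRUE)]
  if (length(unique(lapply(dims, as.integer))) > 1L)
    stop("grid mismatch between masks: ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"), ""),
               collapse = " vs "))
  invisible(TRUE)
}

#' Build the WMH penumbra mask
#'
#' Lesion masks from all timepoints are combined (union), the union is
#' dilated by `radius_mm` in physical units (a voxel joins iff its centre
#' lies within `radius_mm` Euclidean distance of any union-voxel centre,
#' honouring anisotropic voxel sizes), and the baseline WMH is subtracted.
#' The result is intersected with the white matter mask and the exclusion
#' mask (infarct + peri-infarct + non-WM) is removed.
#'
#' @param wmh_masks_by_time list of per-timepoint logical lesion masks
#'   (baseline first).
#' @param baseline_wmh baseline lesion mask.
#' @param wm_mask white matter mask.
#' @param exclusion_mask mask of excluded voxels (may be `NULL`).
#' @param config a [penumbra_config()].
#' @param voxel_size mm per axis.
#' @return logical penumbra mask.
#' @export
build_penumbra <- function(wmh_masks_by_time, baseline_wmh, wm_mask,
                           exclusion_mask = NULL,
                           config = penumbra_config(),
                           voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(config, "penumbra_config"))
  do.call(check_same_grid, c(wmh_masks_by_time,
                             list(baseline_wmh, wm_mask, exclusion_mask)))
  union <- Reduce(`|`, wmh_masks_by_time)
  if (!any(union)) return(array(FALSE, dim(baseline_wmh)))
  pen <- dilate_mm(union, config$radius_mm, voxel_size)
  pen <- pen & !baseline_wmh & wm_mask
  if (!is.null(exclusion_mask)) pen <- pen & !exclusion_mask
  pen
}

#' Classify penumbra voxels as progressing or stable
#'
#' A penumbra voxel is *progressing* iff it is segmented as a new lesion at
#' a later timepoint AND lies in a region of significant FLAIR intensity
#' increase (the AND rule); all remaining penumbra voxels are *stable*.
#'
#' @param penumbra penumbra mask from [build_penumbra()].
#' @param wmh_masks_by_time per-timepoint lesion masks (baseline first).
#' @param significant_increase_mask mask of significant FLAIR-increase
#'   clusters (from [grf_cluster_correct()]); `NULL` counts as all-FALSE.
#' @param wm_mask white matter mask (defines the partition domain).
#' @param baseline_wmh baseline lesion mask (defaults to the first entry of
#'   `wmh_masks_by_time`).
#' @param exclusion_mask excluded voxels.
#' @return object of class `roi_partition`: list of disjoint masks
#'   `baseline_wmh`, `pen_prog`, `pen_stable`, `nawm`, `excluded`.
#' @export
classify_penumbra <- function(penumbra, wmh_masks_by_time,
                              significant_increase_mask = NULL,
                              wm_mask = NULL,
                              baseline_wmh = wmh_masks_by_time[[1]],
                              exclusion_mask = NULL) {
  check_same_grid(penumbra, baseline_wmh, significant_increase_mask, wm_mask)
  newseg <- Reduce(`|`, wmh_masks_by_time[-1],
                   init = array(FALSE, dim(penumbra))) & !baseline_wmh
  if (is.null(significant_increase_mask))
    significant_increase_mask <- array(FALSE, dim(penumbra))
  prog <- penumbra & newseg & significant_increase_mask
  stable <- penumbra & !prog
  if (is.null(wm_mask)) wm_mask <- array(TRUE, dim(penumbra))
  if (is.null(exclusion_mask)) exclusion_mask <- array(FALSE, dim(penumbra))
  excluded <- wm_mask & exclusion_mask
  nawm <- wm_mask & !baseline_wmh & !penumbra & !excluded
  structure(list(baseline_wmh = baseline_wmh & wm_mask & !excluded,
                 pen_prog = prog & !excluded,
                 pen_stable = stable & !excluded,
                 nawm = nawm,
                 excluded = excluded),
            class = "roi_partition")
}

#' Annualized lesion growth from a partition
#'
#' @param partition a `roi_partition`.
#' @param voxel_size mm per axis.
#' @param study_duration_years follow-up duration.
#' @param ticv_vox total intracranial volume in voxels (for the % of TICV).
#' @return list with `ml_per_year` and `pct_ticv_per_year`.
#' @export
annualized_growth <- function(partition, voxel_size, study_duration_years,
                              ticv_vox = NULL) {
  if (study_duration_years <= 0) stop("study duration must be positive")
  vol_ml <- sum(partition$pen_prog) * voxel_ml(voxel_size)
  out <- list(ml_per_year = vol_ml / study_duration_years,
              pct_ticv_per_year = NA_real_)
  if (!is.null(ticv_vox)) {
    if (ticv_vox <= 0) stop("TICV must be positive")
    ticv_ml <- ticv_vox * voxel_ml(voxel_size)
    out$pct_ticv_per_year <- 100 * out$ml_per_year / ticv_ml
  }
  out
}

#' Summarize a partition as a table of volumes
#'
#' @param partition a `roi_partition`.
#' @param voxel_size mm per axis.
#' @param ticv_vox total intracranial voxels (optional).
#' @return data.frame with voxels, ml and percent of TICV per region.
#' @export
partition_summary <- function(partition, voxel_size, ticv_vox = NULL) {
  vox <- vapply(partition, sum, 0L)
  ml <- vox * voxel_ml(voxel_size)
  pct <- if (is.null(ticv_vox)) NA_real_ else
    100 * ml / (ticv_vox * voxel_ml(voxel_size))
  data.frame(region = names(partition), voxels = as.integer(vox),
             ml = ml, pct_ticv = pct, row.names = NULL)
}
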
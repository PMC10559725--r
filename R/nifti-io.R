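## NIfTI-1 round trips (via RNifti) and per-subject export: volumes,
## FSL-dialect bval/bvec, and a JSON ground-truth sidecar.

#' Write a volume as NIfTI-1
#'
#' @param volume 3D or 4D numeric/logical array (logical is written as
#'   integer).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm per axis (length 3).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = c(1, 1, 1)) {
  if (any(!is.finite(volume)))
    stop("refusing to write non-finite voxel values")
  if (is.logical(volume)) volume <- array(as.integer(volume), dim(volume))
  img <- RNifti::asNifti(volume)
  nd <- length(dim(volume))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, nd - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return list with `data` (array) and `voxel_size` (mm, length 3).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = pd[seq_len(min(3L, length(pd)))])
}

#' Export one simulated subject to disk
#'
#' Writes per-timepoint FLAIR and lesion-mask NIfTIs, the tissue label
#' volume, infarct mask, 4D DWI series with `.bval`/`.bvec`, true
#' free-water field, and a JSON sidecar with the ground-truth bookkeeping
#' (timepoints, growth parameters, progression voxel count, covariates).
#'
#' @param subj output of [simulate_subject()].
#' @param dir output directory (created if needed).
#' @return named character vector of written files, invisibly.
#' @export
write_subject <- function(subj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- subj$truth$voxel_size
  files <- c()
  p <- function(...) file.path(dir, paste0(...))
  for (i in seq_along(subj$flair)) {
    f <- p("flair_t", i, ".nii.gz")
    write_volume(subj$flair[[i]], f, vs); files <- c(files, f)
    f <- p("wmh_t", i, ".nii.gz")
    write_volume(subj$seg_masks[[i]], f, vs); files <- c(files, f)
  }
  f <- p("labels.nii.gz")
  write_volume(subj$truth$tissue_labels, f, vs); files <- c(files, f)
  f <- p("infarct.nii.gz")
  write_volume(subj$truth$infarct_mask, f, vs); files <- c(files, f)
  f <- p("fw_true.nii.gz")
  write_volume(subj$truth$fw_field, f, vs); files <- c(files, f)
  if (!is.null(subj$dwi)) {
    for (nm in names(subj$dwi)) {
      f <- p("dwi_", nm, ".nii.gz")
      write_volume(subj$dwi[[nm]], f, vs); files <- c(files, f)
    }
    write_bvalbvec(subj$scheme, p("dwi.bval"), p("dwi.bvec"))
    files <- c(files, p("dwi.bval"), p("dwi.bvec"))
  }
  sidecar <- list(
    subject = subj$truth$subject,
    timepoints = subj$truth$timepoints,
    voxel_size = vs,
    n_progressing = sum(subj$truth$progression_mask),
    growth_params = subj$truth$growth_params[c("mu", "a", "b")],
    covariates = as.list(subj$covariates))
  f <- p("truth.json")
  jsonlite::write_json(sidecar, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
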
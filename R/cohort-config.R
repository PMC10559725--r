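## Cohort configuration for the synthetic longitudinal phantom generator.
## Defaults reproduce the study conditions of a serial-MRI small vessel
## disease cohort: four white matter ROI classes (NAWM, stable penumbra,
## progressing penumbra, baseline WMH) with literature baseline means for
## free water, FA_Tissue, MD_Tissue and GM-normalized FLAIR; a 12-direction
## b = 1000 s/mm^2 shell with 4 b = 0 volumes; five visits over one year;
## and a lesion growth target of 2.9 ml/year.

.roi_levels <- c("csf", "gm", "nawm", "pen_stable", "pen_prog", "wmh")

#' Configuration for a synthetic longitudinal phantom cohort
#'
#' All generative parameters of the simulator, with defaults that encode the
#' emulated study conditions. Identical `seed` + config give a bit-identical
#' cohort.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape voxels per axis (each >= 32).
#' @param voxel_size mm per axis.
#' @param timepoints acquisition times in years since baseline; strictly
#'   increasing, at least 3 values.
#' @param seed integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param flair_noise_sd additive Gaussian noise SD on rendered FLAIR, in
#'   normalized intensity units.
#' @param dwi_snr b=0 signal-to-noise ratio (S0 / noise SD); `Inf` for
#'   noiseless DWI.
#' @param s0 b=0 signal level (arbitrary units).
#' @param roi_fw_means named free-water fraction means per ROI class
#'   (`csf, gm, nawm, pen_stable, pen_prog, wmh`). The four WM classes must
#'   be ordered nawm < pen_stable < pen_prog < wmh and lie in `[0, 1]`.
#' @param roi_flair_means named GM-normalized FLAIR means per ROI class.
#' @param roi_fa_tissue,roi_md_tissue named tissue-tensor FA and MD
#'   (mm^2/s) per ROI class.
#' @param flair_slope_progressing linear FLAIR intensity rise in
#'   progressing voxels, normalized units per year.
#' @param fw_slope_progressing free-water rise in progressing voxels, per
#'   year.
#' @param growth_logit `c(intercept, slope)` of the conversion logit on
#'   baseline free water; when `calibrate_growth = TRUE` it is used as the
#'   starting point of the per-subject calibration.
#' @param calibrate_growth solve intercept/slope/penumbra FW location so
#'   that the expected converted volume matches `target_growth_ml` and the
#'   class-conditional FW means match `roi_fw_means` (default `TRUE`).
#' @param target_growth_ml expected lesion growth in ml per year.
#' @param gain_per_timepoint multiplicative scanner gain per timepoint
#'   (recycled); distinct gains make FLAIR normalization non-trivial.
#' @param fw_jitter_sd smooth within-class free-water jitter SD (NAWM/WMH).
#' @param fa_jitter_sd,md_jitter_sd smooth within-class jitter SD of the
#'   tissue tensor's FA (unitless) and MD (mm^2/s) in white matter
#'   classes; real tissue classes overlap rather than separating cleanly.
#' @param fw_jitter_penumbra latent free-water jitter SD inside the
#'   penumbra, the spread conversion selects on.
#' @param jitter_fwhm_vox FWHM (voxels) of the smooth jitter fields.
#' @param wmh_fraction_ticv baseline WMH volume as a fraction of total
#'   intracranial volume; `0` gives a lesion-free phantom.
#' @param wmh_lobulation_mm amplitude (mm) of the angular modulation that
#'   makes baseline lesions blobby rather than a perfect shell.
#' @param infarct_radius_mm radius of the chronic-infarct exclusion sphere;
#'   `0` for none.
#' @param label_flip_rate probability of flipping a lesion-boundary voxel in
#'   the segmentation masks handed downstream (emulates segmentation error;
#'   default 0 = truth masks).
#' @param penumbra_radius_mm penumbra dilation radius used by the growth
#'   model (and by default downstream), mm.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8L,
                          grid_shape = c(48L, 48L, 48L),
                          voxel_size = c(2.5, 2.5, 2.5),
                          timepoints = c(0, 0.25, 0.5, 0.75, 1),
                          seed = 1L,
                          flair_noise_sd = 0.03,
                          dwi_snr = 40,
                          s0 = 500,
                          roi_fw_means = c(csf = 0.95, gm = 0.15,
                                           nawm = 0.205, pen_stable = 0.285,
                                           pen_prog = 0.379, wmh = 0.520),
                          roi_flair_means = c(csf = 0.35, gm = 1.0,
                                              nawm = 0.928, pen_stable = 0.977,
                                              pen_prog = 1.112, wmh = 1.189),
                          roi_fa_tissue = c(csf = 0, gm = 0,
                                            nawm = 0.479, pen_stable = 0.556,
                                            pen_prog = 0.499, wmh = 0.385),
                          roi_md_tissue = c(csf = 3.0e-3, gm = 0.8e-3,
                                            nawm = 6.06e-4, pen_stable = 6.30e-4,
                                            pen_prog = 6.62e-4, wmh = 6.91e-4),
                          flair_slope_progressing = 0.058,
                          fw_slope_progressing = 0.034,
                          growth_logit = c(-4, 15),
                          calibrate_growth = TRUE,
                          target_growth_ml = 2.9,
                          gain_per_timepoint = c(1, 1.1, 0.95, 1.05, 0.9),
                          fw_jitter_sd = 0.02,
                          fa_jitter_sd = 0.03,
                          md_jitter_sd = 0.4e-4,
                          fw_jitter_penumbra = 0.07,
                          jitter_fwhm_vox = 6,
                          wmh_fraction_ticv = 0.01,
                          wmh_lobulation_mm = 5,
                          infarct_radius_mm = 6,
                          label_flip_rate = 0,
                          penumbra_radius_mm = 3) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3L)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 3L || any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing with at least 3 values")
  for (nm in c("roi_fw_means", "roi_flair_means", "roi_fa_tissue",
               "roi_md_tissue")) {
    v <- get(nm)
    if (!all(.roi_levels %in% names(v)))
      stop(nm, " must be named with: ", paste(.roi_levels, collapse = ", "))
  }
  fw_wm <- roi_fw_means[c("nawm", "pen_stable", "pen_prog", "wmh")]
  if (any(roi_fw_means < 0) || any(roi_fw_means > 1))
    stop("roi_fw_means must lie in [0, 1]")
  if (any(diff(fw_wm) <= 0))
    stop("roi_fw_means must be ordered nawm < pen_stable < pen_prog < wmh")
  if (flair_noise_sd < 0) stop("flair_noise_sd must be non-negative")
  if (dwi_snr <= 0) stop("dwi_snr must be positive")
  if (label_flip_rate < 0 || label_flip_rate > 1)
    stop("label_flip_rate must be in [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
    voxel_size = voxel_size, timepoints = timepoints, seed = as.integer(seed),
    flair_noise_sd = flair_noise_sd, dwi_snr = dwi_snr, s0 = s0,
    roi_fw_means = roi_fw_means[.roi_levels],
    roi_flair_means = roi_flair_means[.roi_levels],
    roi_fa_tissue = roi_fa_tissue[.roi_levels],
    roi_md_tissue = roi_md_tissue[.roi_levels],
    flair_slope_progressing = flair_slope_progressing,
    fw_slope_progressing = fw_slope_progressing,
    growth_logit = growth_logit, calibrate_growth = calibrate_growth,
    target_growth_ml = target_growth_ml,
    gain_per_timepoint = rep(gain_per_timepoint,
                             length.out = length(timepoints)),
    fw_jitter_sd = fw_jitter_sd, fa_jitter_sd = fa_jitter_sd,
    md_jitter_sd = md_jitter_sd, fw_jitter_penumbra = fw_jitter_penumbra,
    jitter_fwhm_vox = jitter_fwhm_vox,
    wmh_fraction_ticv = wmh_fraction_ticv,
    wmh_lobulation_mm = wmh_lobulation_mm,
    infarct_radius_mm = infarct_radius_mm,
    label_flip_rate = label_flip_rate,
    penumbra_radius_mm = penumbra_radius_mm), class = "cohort_config")
}

## Deterministic sub-stream seed for (subject, stage); kept below 2^31-1.
derive_seed <- function(seed, subject, stage) {
  as.integer((as.numeric(seed) * 7919 + subject * 104729 + stage * 131) %%
               2147483629)
}

#' Volume of one voxel in ml
#' @param config a `cohort_config` (or numeric voxel_size vector).
#' @export
voxel_ml <- function(config) {
  vs <- if (inherits(config, "cohort_config")) config$voxel_size else config
  prod(vs) / 1000
}
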
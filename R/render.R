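## Forward rendering of the phantom into FLAIR and DWI volumes.

#' Render a FLAIR volume at a given acquisition time
#'
#' Voxel intensity is `gain_t * (class mean + progression slope * t)` plus
#' additive Gaussian noise of SD `config$flair_noise_sd` inside the
#' intracranial volume. Gains differ across timepoints so downstream
#' GM-normalization is non-trivial. Background voxels stay at zero.
#'
#' @param truth grown `ground_truth` (see [grow_lesions()]).
#' @param t acquisition time in years; must be one of `config$timepoints`.
#' @param config the [cohort_config()].
#' @param noise_sd noise SD override (default from config; `0` = noiseless).
#' @return 3D intensity array.
#' @export
render_flair <- function(truth, t, config, noise_sd = config$flair_noise_sd) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(truth$flair_mean_field))
    stop("run grow_lesions() before rendering")
  it <- match(TRUE, abs(config$timepoints - t) < 1e-9)
  if (is.na(it)) stop("t = ", t, " is not one of config$timepoints")
  if (noise_sd < 0) stop("noise sd must be non-negative")
  gain <- config$gain_per_timepoint[it]
  vol <- gain * (truth$flair_mean_field + truth$flair_slope_field * t)
  if (noise_sd > 0) {
    set.seed(derive_seed(config$seed, truth$subject, 10L + it))
    sel <- truth$tissue_labels != LBL_BG
    vol[sel] <- vol[sel] + rnorm(sum(sel), sd = noise_sd)
  }
  vol
}

#' Render a DWI series at a given acquisition time
#'
#' Per-voxel two-compartment signal
#' `S(b, g) = S0 (f e^{-b d_fw} + (1 - f) e^{-b g'Dg})` with the true
#' free-water field at time `t` (baseline plus any progression slope) and
#' the true tissue tensor, plus Rician noise at `S0 / snr` (magnitude MRI;
#' a Gaussian option exists for noiseless-oracle work via [add_noise()]).
#'
#' @param truth grown `ground_truth`.
#' @param scheme an [acquisition_scheme()].
#' @param config the [cohort_config()].
#' @param t acquisition time in years (default baseline).
#' @param snr SNR override; `Inf` for noiseless.
#' @return 4D array `(x, y, z, volume)`; background voxels are zero.
#' @export
render_dwi <- function(truth, scheme, config, t = 0,
                       snr = config$dwi_snr) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(scheme, "acquisition_scheme"))
  it <- match(TRUE, abs(config$timepoints - t) < 1e-9)
  if (is.na(it)) stop("t = ", t, " is not one of config$timepoints")
  d <- truth$dim
  nvol <- length(scheme$bvals)
  sel <- which(truth$tissue_labels != LBL_BG)
  fw_t <- pmin(pmax(truth$fw_field[sel] +
                      truth$fw_slope_field[sel] * t, 0), 1)
  sig <- bitensor_signal(config$s0, fw_t,
                         truth$tensor_d6[sel, , drop = FALSE], scheme)
  out <- array(0, c(d, nvol))
  flat <- matrix(out, prod(d), nvol)
  flat[sel, ] <- sig
  if (is.finite(snr)) {
    set.seed(derive_seed(config$seed, truth$subject, 30L + it))
    flat[sel, ] <- add_noise(flat[sel, , drop = FALSE],
                             sd = config$s0 / snr, model = "rician")
  }
  array(flat, c(d, nvol))
}

## Subject-level covariates emulating the cohort demographics: age 71 (9),
## 31% female, race mix, two MRI sites. Exchangeable by construction: they
## do not influence lesion growth.
simulate_covariates <- function(config, subject) {
  set.seed(derive_seed(config$seed, subject, 4L))
  data.frame(
    subject = subject,
    age = round(rnorm(1, 71, 9)),
    sex = sample(c("M", "F"), 1, prob = c(0.69, 0.31)),
    race = sample(c("White", "Black", "Hispanic"), 1,
                  prob = c(0.77, 0.15, 0.08)),
    site = sample(c("site1", "site2"), 1),
    stringsAsFactors = FALSE)
}

#' Simulate one subject of the longitudinal phantom cohort
#'
#' @param config a [cohort_config()].
#' @param subject subject index.
#' @param scheme acquisition scheme (default [default_scheme()]).
#' @param dwi which timepoints get DWI: `"all"`, `"baseline"` or `"none"`.
#' @return list with `truth`, `flair` (list over timepoints), `dwi` (list
#'   over rendered timepoints or `NULL`), `scheme`, `covariates`,
#'   `seg_masks` (the segmentation handed downstream) and `config`.
#' @export
simulate_subject <- function(config, subject = 1L, scheme = default_scheme(),
                             dwi = c("all", "baseline", "none")) {
  dwi <- match.arg(dwi)
  truth <- grow_lesions(make_anatomy(config, subject), config)
  flair <- lapply(config$timepoints, function(t) render_flair(truth, t, config))
  names(flair) <- names(truth$wmh_mask_t)
  dwi_tp <- switch(dwi, all = config$timepoints, baseline = config$timepoints[1],
                   none = numeric(0))
  dwis <- NULL
  if (length(dwi_tp)) {
    dwis <- lapply(dwi_tp, function(t) render_dwi(truth, scheme, config, t))
    names(dwis) <- paste0("t", match(dwi_tp, config$timepoints))
  }
  cov <- simulate_covariates(config, subject)
  cov$baseline_wmh_ml <- sum(truth$wmh_baseline) * voxel_ml(config)
  list(truth = truth, flair = flair, dwi = dwis, scheme = scheme,
       covariates = cov, seg_masks = segmentation_masks(truth, config),
       config = config)
}

#' Simulate a full cohort
#'
#' @inheritParams simulate_subject
#' @return list with `subjects` (list of [simulate_subject()] outputs) and
#'   `covariates` (one row per subject).
#' @export
simulate_cohort <- function(config, scheme = default_scheme(),
                            dwi = c("all", "baseline", "none")) {
  dwi <- match.arg(dwi)
  subjects <- lapply(seq_len(config$n_subjects), function(s)
    simulate_subject(config, s, scheme, dwi))
  list(subjects = subjects,
       covariates = do.call(rbind, lapply(subjects, `[[`, "covariates")),
       config = config, scheme = scheme)
}
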
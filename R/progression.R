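## Localizing lesion progression: GM-normalization, non-local means
## denoising, per-voxel intensity slopes, and the stable-NAWM Z transform.

#' Normalize a FLAIR volume to the mean gray matter intensity
#'
#' Every voxel is divided by the mean intensity over the GM mask, so
#' per-timepoint scanner gain cancels and intensities are comparable
#' across visits.
#'
#' @param volume 3D intensity array.
#' @param gm_mask logical 3D array (non-empty, positive mean).
#' @return normalized volume (mean over GM = 1).
#' @export
normalize_flair <- function(volume, gm_mask) {
  check_same_grid(volume, gm_mask)
  if (!any(gm_mask)) stop("gray matter mask is empty")
  m <- mean(volume[gm_mask])
  if (!is.finite(m) || m <= 0)
    stop("gray matter mean intensity must be positive, got ", m)
  volume / m
}

#' Estimate the noise standard deviation of a volume
#'
#' Robust MAD of first differences along x within the mask, divided by
#' sqrt(2): first differences of a (locally) smooth image are dominated by
#' noise.
#' @param volume 3D array.
#' @param mask logical array (default: whole volume).
#' @return estimated noise SD.
#' @export
estimate_noise_sd <- function(volume, mask = NULL) {
  d <- dim(volume)
  dif <- volume[-1, , ] - volume[-d[1], , ]
  if (!is.null(mask)) {
    both <- mask[-1, , ] & mask[-d[1], , ]
    dif <- dif[both]
  }
  stats::mad(dif) / sqrt(2)
}

#' Non-local means denoising
#'
#' Standard non-local means: each voxel is replaced by a weighted average
#' of voxels in its search window, with weights
#' `exp(-max(d2 - 2 sigma^2, 0) / h^2)` where `d2` is the mean squared
#' patch difference. The self-weight is the maximum neighbour weight.
#' `h = 0` returns the input exactly.
#'
#' @param volume 3D array.
#' @param patch_radius patch half-width (voxels).
#' @param search_radius search window half-width (voxels).
#' @param h filtering strength, intensity units; `NULL` uses
#'   `1.5 * estimate_noise_sd(volume, mask)`.
#' @param sigma noise SD used in the distance offset; defaults to the same
#'   estimate.
#' @param mask restrict the noise estimate to this mask.
#' @return denoised volume.
#' @export
denoise_nlm <- function(volume, patch_radius = 1, search_radius = 2,
                        h = NULL, sigma = NULL, mask = NULL) {
  if (is.null(sigma)) sigma <- estimate_noise_sd(volume, mask)
  if (is.null(h)) h <- 1.5 * sigma
  if (h < 0) stop("h must be non-negative")
  if (h == 0) return(volume)
  npatch <- (2 * patch_radius + 1)^3
  offs <- as.matrix(expand.grid(dx = -search_radius:search_radius,
                                dy = -search_radius:search_radius,
                                dz = -search_radius:search_radius))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  wsum <- array(0, dim(volume))
  vsum <- array(0, dim(volume))
  wmax <- array(0, dim(volume))
  for (i in seq_len(nrow(offs))) {
    shifted <- shift_array(volume, offs[i, ], fill = NA_real_)
    diff2 <- (volume - shifted)^2
    valid <- !is.na(diff2)
    diff2[!valid] <- 0
    d2 <- box_sum(diff2, patch_radius) / pmax(box_sum(valid * 1, patch_radius), 1)
    w <- exp(-pmax(d2 - 2 * sigma^2, 0) / h^2)
    w[is.na(shifted)] <- 0
    shifted[is.na(shifted)] <- 0
    wsum <- wsum + w
    vsum <- vsum + w * shifted
    wmax <- pmax(wmax, w)
  }
  wself <- pmax(wmax, 1e-12)
  (vsum + wself * volume) / (wsum + wself)
}

#' Non-local means denoising of a longitudinal series with shared weights
#'
#' Computes the non-local means weights once, from the across-time mean
#' image, and applies the same weights to every timepoint. Per-timepoint
#' weights would drift as lesions evolve (a voxel's neighbourhood changes
#' similarity over time), which injects artificial intensity trends at
#' tissue boundaries; shared weights make the denoiser a single fixed
#' linear operator, so per-voxel slopes are smoothed but never invented.
#'
#' @param series list of 3D volumes (same grid), one per timepoint.
#' @param patch_radius,search_radius window sizes (voxels).
#' @param h filtering strength; `NULL` uses `1.5 *` the noise SD of the
#'   first volume scaled down by `sqrt(length(series))` (the mean image is
#'   less noisy).
#' @param mask restrict the noise estimate to this mask.
#' @return list of denoised volumes.
#' @export
denoise_nlm_series <- function(series, patch_radius = 1, search_radius = 2,
                               h = NULL, mask = NULL) {
  do.call(check_same_grid, series)
  nt <- length(series)
  mvol <- Reduce(`+`, series) / nt
  sigma <- estimate_noise_sd(mvol, mask)
  if (is.null(h)) h <- 1.5 * sigma
  if (h < 0) stop("h must be non-negative")
  if (h == 0) return(series)
  offs <- as.matrix(expand.grid(dx = -search_radius:search_radius,
                                dy = -search_radius:search_radius,
                                dz = -search_radius:search_radius))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  wsum <- array(0, dim(mvol))
  w2sum <- array(0, dim(mvol))
  wmax <- array(0, dim(mvol))
  vsum <- lapply(series, function(v) array(0, dim(mvol)))
  for (i in seq_len(nrow(offs))) {
    shifted <- shift_array(mvol, offs[i, ], fill = NA_real_)
    diff2 <- (mvol - shifted)^2
    valid <- !is.na(diff2)
    diff2[!valid] <- 0
    d2 <- box_sum(diff2, patch_radius) /
      pmax(box_sum(valid * 1, patch_radius), 1)
    w <- exp(-pmax(d2 - 2 * sigma^2, 0) / h^2)
    w[is.na(shifted)] <- 0
    wsum <- wsum + w
    w2sum <- w2sum + w^2
    wmax <- pmax(wmax, w)
    for (t in seq_len(nt))
      vsum[[t]] <- vsum[[t]] + w * shift_array(series[[t]], offs[i, ], fill = 0)
  }
  wself <- pmax(wmax, 1e-12)
  out <- lapply(seq_len(nt), function(t)
    (vsum[[t]] + wself * series[[t]]) / (wsum + wself))
  ## Per-voxel noise scale of the (fixed, linear) denoising operator: for
  ## iid input noise, output noise SD scales as the root sum of squared
  ## normalized weights. Boundary voxels average fewer neighbours, so a
  ## single global null SD would understate their variance; this map lets
  ## the Z transform standardize heteroscedastically.
  attr(out, "noise_scale") <- sqrt(w2sum + wself^2) / (wsum + wself)
  out
}

#' Per-voxel OLS slope of intensity over time
#'
#' @param series list of 3D volumes, one per timepoint (same grid).
#' @param times acquisition times in years (length = number of volumes,
#'   at least 2 distinct values).
#' @param mask logical array; slopes are computed inside it (NA outside).
#' @return list with `beta` (3D slope array, 1/year), `n_timepoints`,
#'   `times`.
#' @export
fit_voxel_slopes <- function(series, times, mask = NULL) {
  if (length(series) != length(times))
    stop("series and times lengths differ")
  if (length(unique(times)) < 2L) stop("need at least 2 distinct times")
  do.call(check_same_grid, series)
  tc <- times - mean(times)
  sxx <- sum(tc^2)
  beta <- array(0, dim(series[[1]]))
  for (i in seq_along(series)) beta <- beta + tc[i] * series[[i]]
  beta <- beta / sxx
  if (!is.null(mask)) beta[!mask] <- NA_real_
  list(beta = beta, n_timepoints = length(times), times = times)
}

#' Null slope distribution from stable NAWM
#'
#' Mean and SD of the per-voxel slopes within the stable-NAWM mask; the
#' empirical null against which penumbra slopes are standardized.
#'
#' @param slopes output of [fit_voxel_slopes()] (or a 3D slope array).
#' @param nawm_mask logical array of stable NAWM voxels.
#' @param min_voxels required NAWM voxel count (default 100).
#' @return list with `mu_nawm`, `sigma_nawm`, `n`.
#' @export
estimate_null <- function(slopes, nawm_mask, min_voxels = 100) {
  beta <- if (is.list(slopes)) slopes$beta else slopes
  check_same_grid(beta, nawm_mask)
  x <- beta[nawm_mask]
  x <- x[is.finite(x)]
  if (length(x) < min_voxels)
    stop("need at least ", min_voxels, " NAWM voxels, got ", length(x))
  s <- sd(x)
  if (!is.finite(s) || s <= 0)
    stop("zero variance in NAWM slopes (degenerate phantom)")
  list(mu_nawm = mean(x), sigma_nawm = s, n = length(x))
}

#' Convert slopes to Z-statistics against the NAWM null
#'
#' `Z = (beta - mu_nawm) / sigma_nawm` per voxel. When the series was
#' denoised with a spatially adaptive (but fixed, linear) operator, the
#' per-voxel slope noise is heteroscedastic; passing the operator's
#' `noise_scale` map (see [denoise_nlm_series()]) together with the NAWM
#' mask standardizes each voxel by `sigma_nawm * r_v / r_rms(NAWM)`, which
#' keeps the NAWM Z distribution at unit scale while giving
#' less-averaged boundary voxels their correct, larger null SD.
#'
#' @param slopes output of [fit_voxel_slopes()] (or a 3D slope array).
#' @param null output of [estimate_null()].
#' @param noise_scale optional per-voxel relative noise SD map.
#' @param nawm_mask required with `noise_scale`: normalizes the scale map
#'   to RMS 1 over the null region.
#' @return 3D Z array.
#' @export
slopes_to_z <- function(slopes, null, noise_scale = NULL, nawm_mask = NULL) {
  beta <- if (is.list(slopes)) slopes$beta else slopes
  stopifnot(is.finite(null$sigma_nawm), null$sigma_nawm > 0)
  if (is.null(noise_scale)) return((beta - null$mu_nawm) / null$sigma_nawm)
  if (is.null(nawm_mask))
    stop("nawm_mask is required when noise_scale is given")
  r <- noise_scale / sqrt(mean(noise_scale[nawm_mask]^2))
  (beta - null$mu_nawm) / (null$sigma_nawm * pmax(r, 1e-6))
}
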
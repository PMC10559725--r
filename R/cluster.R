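## Cluster-level inference on Z-statistic maps using Gaussian random field
## (GRF) theory, with a permutation mode as the model-free calibration
## alternative.
##
## Formula set (Friston/Worsley family), pinned here because numbering
## conventions vary across references:
##   * smoothness: per axis j, lambda_j = Var(du/dx_j) of the standardized
##     field; FWHM_j = sqrt(4 log 2 / lambda_j) voxels.
##   * RESELs: R = V / prod(FWHM_j).
##   * expected cluster count above z (3D Euler characteristic density):
##       E[m] = R * (4 log 2)^{3/2} * (2*pi)^{-2} * (z^2 - 1) * exp(-z^2/2)
##   * expected suprathreshold volume: E[N] = V * (1 - Phi(z)) voxels.
##   * cluster extent tail: P(K >= k) = exp(-beta * k^{2/3}) with
##       beta = (Gamma(5/2) * E[m] / E[N])^{2/3}
##   * cluster-level p for extent k: p = 1 - exp(-E[m] * P(K >= k)).

#' Estimate field smoothness (FWHM) from a standardized field
#'
#' Gradient-variance estimator: the variance of the first spatial
#' difference of the (globally standardized) field gives
#' `FWHM_j = sqrt(4 log 2 / lambda_j)` voxels per axis. Values are floored
#' at 1 voxel (GRF is invalid below the lattice scale) with a warning.
#'
#' @param field 3D array (a Z map or standardized residual field), or a
#'   list of such arrays whose gradient variances are pooled.
#' @param mask logical array; differences use voxel pairs inside the mask.
#' @return list with `fwhm_vox` (per axis), `resels_per_voxel`, and
#'   `n_pairs` used per axis.
#' @export
estimate_fwhm <- function(field, mask) {
  fields <- if (is.list(field)) field else list(field)
  lam <- numeric(3)
  npairs <- integer(3)
  for (ax in 1:3) {
    num <- 0; den <- 0
    for (u in fields) {
      u <- (u - mean(u[mask])) / sd(u[mask])
      d <- dim(u)
      idx1 <- slice.index(u, ax) < d[ax]
      off <- c(0, 0, 0); off[ax] <- -1
      du <- shift_array(u, off, fill = NA_real_) - u
      ok <- mask & shift_array(mask, off, fill = FALSE) & idx1 &
        !is.na(du)
      num <- num + sum(du[ok]^2)
      den <- den + sum(ok)
    }
    lam[ax] <- num / max(den, 1)
    npairs[ax] <- den
  }
  fwhm <- sqrt(4 * log(2) / pmax(lam, .Machine$double.eps))
  if (any(fwhm < 1)) {
    warning("estimated FWHM below 1 voxel on axis ",
            paste(which(fwhm < 1), collapse = ","),
            "; floored at 1 voxel (GRF invalid below lattice scale)")
    fwhm <- pmax(fwhm, 1)
  }
  list(fwhm_vox = fwhm, resels_per_voxel = 1 / prod(fwhm), n_pairs = npairs)
}

## Expected number of clusters above z in a field of R RESELs (3D EC
## density), and the extent-tail exponent.
grf_expected_clusters <- function(z, resels) {
  resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (z^2 - 1) * exp(-z^2 / 2)
}

#' GRF cluster-extent p-value
#'
#' @param k cluster size in voxels.
#' @param z_thresh cluster-forming threshold.
#' @param volume_vox search volume in voxels.
#' @param fwhm_vox smoothness per axis in voxels.
#' @return cluster-level p-value in (0, 1].
#' @export
grf_cluster_p <- function(k, z_thresh, volume_vox, fwhm_vox) {
  resels <- volume_vox / prod(fwhm_vox)
  Em <- max(grf_expected_clusters(z_thresh, resels), .Machine$double.xmin)
  En <- volume_vox * pnorm(z_thresh, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * Em / En)^(2 / 3)
  p_ext <- exp(-beta * k^(2 / 3))
  pmin(pmax(1 - exp(-Em * p_ext), .Machine$double.xmin), 1)
}

#' Cluster-correct a Z map with Gaussian random field theory
#'
#' Thresholds the map at `|Z| >= z_thresh` (positive and negative
#' excursions handled separately), labels connected components, assigns
#' each cluster a GRF cluster-extent p-value, and keeps clusters with
#' `p < p_thresh`.
#'
#' @param zmap 3D Z-statistic array (finite inside the mask).
#' @param analysis_mask logical array defining the search volume.
#' @param z_thresh cluster-forming threshold (default 2.3).
#' @param p_thresh cluster-level threshold (default 0.01).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param two_sided test decreases as well as increases (default TRUE).
#' @param smooth_from field(s) for the smoothness estimate: `NULL` uses
#'   the Z map itself; otherwise a 3D array or list of arrays (e.g.
#'   standardized per-timepoint residual fields).
#' @param fwhm_vox optionally fix the smoothness instead of estimating it.
#' @return object of class `cluster_result`: `clusters` (data.frame with
#'   label, sign, size_vox, size_resels, peak_z, p), `labels` (integer 3D
#'   array of significant clusters), `significant_increase` /
#'   `significant_decrease` masks, `fwhm_vox`, `resels`.
#' @export
grf_cluster_correct <- function(zmap, analysis_mask, z_thresh = 2.3,
                                p_thresh = 0.01, connectivity = 26,
                                two_sided = TRUE, smooth_from = NULL,
                                fwhm_vox = NULL) {
  check_same_grid(zmap, analysis_mask)
  if (any(!is.finite(zmap[analysis_mask])))
    stop("Z map contains non-finite values inside the mask")
  if (is.null(fwhm_vox)) {
    sm <- estimate_fwhm(if (is.null(smooth_from)) zmap else smooth_from,
                        analysis_mask)
    fwhm_vox <- sm$fwhm_vox
  }
  V <- sum(analysis_mask)
  resels <- V / prod(fwhm_vox)

  signs <- if (two_sided) c(1, -1) else 1
  rows <- list()
  labels <- array(0L, dim(zmap))
  sig_inc <- array(FALSE, dim(zmap))
  sig_dec <- array(FALSE, dim(zmap))
  next_label <- 0L
  for (sgn in signs) {
    exc <- analysis_mask & (sgn * zmap >= z_thresh)
    if (!any(exc)) next
    comp <- label_components(exc, connectivity)
    for (ci in seq_len(comp$n)) {
      vox <- comp$labels == ci
      k <- comp$sizes[ci]
      p <- grf_cluster_p(k, z_thresh, V, fwhm_vox)
      if (p < p_thresh) {
        next_label <- next_label + 1L
        labels[vox] <- next_label
        if (sgn > 0) sig_inc[vox] <- TRUE else sig_dec[vox] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          label = next_label, sign = ifelse(sgn > 0, "increase", "decrease"),
          size_vox = k, size_resels = k / prod(fwhm_vox),
          peak_z = sgn * max(sgn * zmap[vox]), p = p)
      }
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), sign = character(0),
               size_vox = integer(0), size_resels = numeric(0),
               peak_z = numeric(0), p = numeric(0))
  structure(list(clusters = clusters, labels = labels,
                 significant_increase = sig_inc,
                 significant_decrease = sig_dec,
                 fwhm_vox = fwhm_vox, resels = resels,
                 z_thresh = z_thresh, p_thresh = p_thresh),
            class = "cluster_result")
}

#' Permutation-mode cluster inference (calibration oracle for GRF)
#'
#' Recomputes the slope -> Z -> threshold -> largest-cluster statistic
#' under permutations of the acquisition-time order (which breaks any true
#' time trend while preserving the spatial noise structure) and returns
#' the null distribution of the maximum cluster extent, plus permutation
#' p-values for the observed clusters.
#'
#' @param series list of per-timepoint normalized (and denoised) volumes.
#' @param times acquisition times in years.
#' @param analysis_mask search mask.
#' @param nawm_mask stable-NAWM mask for the null standardization.
#' @param z_thresh cluster-forming threshold.
#' @param connectivity neighbour rule.
#' @param n_perm number of permutations (time orderings are resampled
#'   without replacement from the non-identity permutations).
#' @param two_sided threshold `|Z|` rather than `Z`.
#' @return list with `max_null` (null max cluster sizes), `observed`
#'   (observed cluster sizes, decreasing), `p` (permutation p per observed
#'   cluster: `(1 + #{null >= k}) / (n_perm + 1)`).
#' @export
cluster_permutation_test <- function(series, times, analysis_mask, nawm_mask,
                                     z_thresh = 2.3, connectivity = 26,
                                     n_perm = 99, two_sided = TRUE) {
  cluster_sizes <- function(ord) {
    sl <- fit_voxel_slopes(series, times[ord])
    nl <- estimate_null(sl, nawm_mask)
    z <- slopes_to_z(sl, nl)
    exc <- analysis_mask & (if (two_sided) abs(z) else z) >= z_thresh
    if (!any(exc)) return(integer(0))
    sort(label_components(exc, connectivity)$sizes, decreasing = TRUE)
  }
  obs <- cluster_sizes(seq_along(times))
  max_null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    ord <- sample(length(times))
    while (all(ord == seq_along(times))) ord <- sample(length(times))
    cs <- cluster_sizes(ord)
    max_null[i] <- if (length(cs)) cs[1] else 0
  }
  p <- vapply(obs, function(k) (1 + sum(max_null >= k)) / (n_perm + 1), 0)
  list(max_null = max_null, observed = obs, p = p)
}
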
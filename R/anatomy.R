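## Phantom anatomy and lesion growth. Geometry is deliberately concentric /
## blob-based rather than brain-shaped: the downstream statistics are
## geometry-agnostic, and the simple geometry buys exact bookkeeping of
## every voxel's class and fate.

## Tissue label codes
LBL_BG <- 0L; LBL_CSF <- 1L; LBL_GM <- 2L; LBL_WM <- 3L

## ROI class codes (indices into .roi_levels)
ROI_CSF <- 1L; ROI_GM <- 2L; ROI_NAWM <- 3L
ROI_PEN_STABLE <- 4L; ROI_PEN_PROG <- 5L; ROI_WMH <- 6L

## mm distance of every voxel centre from the grid centre, as an array.
radial_mm <- function(grid_shape, voxel_size) {
  cx <- (grid_shape + 1) / 2
  dx <- (seq_len(grid_shape[1]) - cx[1]) * voxel_size[1]
  dy <- (seq_len(grid_shape[2]) - cx[2]) * voxel_size[2]
  dz <- (seq_len(grid_shape[3]) - cx[3]) * voxel_size[3]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  sqrt(r2)
}

## Smooth standardized Gaussian random field (mean 0, SD 1 over the grid).
smooth_field <- function(grid_shape, fwhm_vox) {
  u <- array(rnorm(prod(grid_shape)), grid_shape)
  u <- gauss_smooth(u, fwhm_vox, normalize = FALSE)
  (u - mean(u)) / sd(u)
}

#' Generate one subject's phantom anatomy
#'
#' Builds nested geometry (central CSF "ventricle", white matter shell,
#' gray matter rim), seeds blobby periventricular baseline WMH lesions
#' covering `wmh_fraction_ticv` of the intracranial volume, places a
#' spherical chronic-infarct exclusion zone, and fills the true free-water
#' and tissue-tensor fields from the per-class means plus smooth
#' within-class jitter.
#'
#' @param config a [cohort_config()].
#' @param subject subject index (>= 1); fixes the random stream together
#'   with `config$seed`.
#' @return object of class `ground_truth`: tissue labels, baseline WMH
#'   mask, infarct mask, free-water field, tensor field (n x 6), and
#'   bookkeeping fields filled in by [grow_lesions()].
#' @export
make_anatomy <- function(config, subject = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  d <- config$grid_shape
  vs <- config$voxel_size
  if (any(d < 32L))
    stop("grid too small to contain all tissue classes: need >= 32 voxels ",
         "per axis, got ", paste(d, collapse = "x"))
  set.seed(derive_seed(config$seed, subject, 1L))

  r <- radial_mm(d, vs)
  rmax <- min(d * vs) / 2
  r_vent <- 0.26 * rmax
  r_wm   <- 0.80 * rmax
  r_icv  <- 0.92 * rmax

  labels <- array(LBL_BG, d)
  labels[r < r_icv] <- LBL_GM
  labels[r < r_wm]  <- LBL_WM
  labels[r < r_vent] <- LBL_CSF

  ticv_vox <- sum(labels != LBL_BG)

  ## Baseline WMH: lowest "periventricular score" voxels; the smooth angular
  ## modulation turns the thin shell into confluent blobs abutting the CSF.
  wmh <- array(FALSE, d)
  n_wmh <- round(config$wmh_fraction_ticv * ticv_vox)
  if (n_wmh > 0) {
    mod <- smooth_field(d, config$jitter_fwhm_vox * 2)
    score <- (r - r_vent) + config$wmh_lobulation_mm * mod
    score[labels != LBL_WM] <- Inf
    thr <- sort(score[is.finite(score)])[n_wmh]
    wmh[score <= thr & labels == LBL_WM] <- TRUE
  }

  ## Chronic infarct: small sphere in the WM shell, diametrically placed in
  ## +x so it rarely touches the periventricular lesions.
  infarct <- array(FALSE, d)
  if (config$infarct_radius_mm > 0) {
    cx <- (d + 1) / 2
    centre_mm <- c((r_vent + r_wm) / 2, 0, 0)
    dx <- (seq_len(d[1]) - cx[1]) * vs[1] - centre_mm[1]
    dy <- (seq_len(d[2]) - cx[2]) * vs[2] - centre_mm[2]
    dz <- (seq_len(d[3]) - cx[3]) * vs[3] - centre_mm[3]
    ri <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
    infarct[ri <= config$infarct_radius_mm & labels == LBL_WM & !wmh] <- TRUE
  }

  ## True free water: class means + smooth within-class jitter, in [0, 1].
  fwm <- config$roi_fw_means
  fw <- array(0, d)
  fw[labels == LBL_CSF] <- fwm[["csf"]]
  fw[labels == LBL_GM]  <- fwm[["gm"]]
  fw[labels == LBL_WM]  <- fwm[["nawm"]]
  fw[wmh] <- fwm[["wmh"]]
  jit <- smooth_field(d, config$jitter_fwhm_vox) * config$fw_jitter_sd
  sel <- labels != LBL_BG
  fw[sel] <- pmin(pmax(fw[sel] + jit[sel], 0.01), 0.99)

  ## Tissue tensor field: anisotropic in WM with a smoothly varying (radial)
  ## principal axis; isotropic in GM/CSF.
  roi0 <- array(0L, d)
  roi0[labels == LBL_CSF] <- ROI_CSF
  roi0[labels == LBL_GM] <- ROI_GM
  roi0[labels == LBL_WM] <- ROI_NAWM
  roi0[wmh] <- ROI_WMH
  fa_jit <- smooth_field(d, config$jitter_fwhm_vox) * config$fa_jitter_sd
  md_jit <- smooth_field(d, config$jitter_fwhm_vox) * config$md_jitter_sd
  tensor <- build_tensor_field(roi0, config, fa_jit, md_jit)

  structure(list(
    subject = as.integer(subject), dim = d, voxel_size = vs,
    timepoints = config$timepoints,
    tissue_labels = labels, wmh_baseline = wmh, infarct_mask = infarct,
    fw_field = fw, tensor_d6 = tensor, ticv_vox = ticv_vox,
    fa_jitter = fa_jit, md_jitter = md_jit,
    ## filled by grow_lesions():
    wmh_mask_t = NULL, progression_mask = NULL, conversion_time = NULL,
    roi_class = roi0, flair_mean_field = NULL, flair_slope_field = NULL,
    fw_slope_field = NULL, penumbra_mask = NULL, growth_params = NULL),
    class = "ground_truth")
}

## Tensor elements for every labelled voxel given current ROI classes.
## fa_jit / md_jit are smooth zero-mean within-class jitter fields applied
## in the white matter classes only (real tissue classes overlap).
build_tensor_field <- function(roi_class, config, fa_jit = NULL,
                               md_jit = NULL) {
  d <- dim(roi_class)
  n <- prod(d)
  tensor <- matrix(0, n, 6)
  ## radial principal axis
  cx <- (d + 1) / 2
  gx <- array(rep((seq_len(d[1]) - cx[1]) * config$voxel_size[1],
                  times = d[2] * d[3]), d)
  gy <- array(rep(rep((seq_len(d[2]) - cx[2]) * config$voxel_size[2],
                      each = d[1]), times = d[3]), d)
  gz <- array(rep((seq_len(d[3]) - cx[3]) * config$voxel_size[3],
                  each = d[1] * d[2]), d)
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  nrm[nrm == 0] <- 1
  ax <- cbind(as.vector(gx / nrm), as.vector(gy / nrm), as.vector(gz / nrm))
  ax[rowSums(ax^2) == 0, 1] <- 1
  wm_classes <- c(ROI_NAWM, ROI_PEN_STABLE, ROI_PEN_PROG, ROI_WMH)
  for (k in seq_along(.roi_levels)) {
    idx <- which(roi_class == k)
    if (!length(idx)) next
    fa <- rep(config$roi_fa_tissue[[.roi_levels[k]]], length(idx))
    md <- rep(config$roi_md_tissue[[.roi_levels[k]]], length(idx))
    if (k %in% wm_classes) {
      if (!is.null(fa_jit)) fa <- pmin(pmax(fa + fa_jit[idx], 0.05), 0.95)
      if (!is.null(md_jit)) md <- pmax(md + md_jit[idx], 1e-4)
    }
    if (all(fa == 0)) {
      tensor[idx, 1:3] <- md
    } else {
      delta <- fa * sqrt(3 / (9 - 6 * fa^2))
      l1 <- md * (1 + 2 * delta); l2 <- md * (1 - delta)
      v <- ax[idx, , drop = FALSE]
      tensor[idx, 1] <- l2 + (l1 - l2) * v[, 1]^2
      tensor[idx, 2] <- l2 + (l1 - l2) * v[, 2]^2
      tensor[idx, 3] <- l2 + (l1 - l2) * v[, 3]^2
      tensor[idx, 4] <- (l1 - l2) * v[, 1] * v[, 2]
      tensor[idx, 5] <- (l1 - l2) * v[, 1] * v[, 3]
      tensor[idx, 6] <- (l1 - l2) * v[, 2] * v[, 3]
    }
  }
  tensor
}

## Solve (mu, a, b) so that over the latent penumbra FW field
## f_i = mu + sigma * u_i the logistic conversion weights w_i = plogis(a + b f_i)
## satisfy: mean(w) = q, E[f | convert] = m_prog, E[f | stable] = m_stable.
calibrate_growth_logit <- function(u, sigma, q, m_prog, m_stable, start_logit) {
  q <- min(max(q, 1e-6), 1 - 1e-6)
  obj <- function(par) {
    mu <- par[1]; a <- par[2]; b <- exp(par[3])
    f <- pmin(pmax(mu + sigma * u, 0.02), 0.98)
    w <- plogis(a + b * f)
    sw <- sum(w); sn <- sum(1 - w)
    r1 <- mean(w) - q
    r2 <- sum(w * f) / sw - m_prog
    r3 <- sum((1 - w) * f) / sn - m_stable
    r1^2 + r2^2 + r3^2
  }
  mu0 <- q * m_prog + (1 - q) * m_stable
  b0 <- max(start_logit[2], 1)
  a0 <- qlogis(q) - b0 * mu0
  fit <- optim(c(mu0, a0, log(b0)), obj,
               control = list(maxit = 2000, reltol = 1e-12))
  ## polish from a second start if poorly converged
  if (fit$value > 1e-8) {
    fit2 <- optim(c(mu0, qlogis(q) - 30 * mu0, log(30)), obj,
                  control = list(maxit = 4000, reltol = 1e-12))
    if (fit2$value < fit$value) fit <- fit2
  }
  list(mu = fit$par[1], a = fit$par[2], b = exp(fit$par[3]),
       residual = fit$value)
}

#' Grow lesions into the penumbra across follow-up timepoints
#'
#' Computes the penumbra (a `penumbra_radius_mm` shell around the baseline
#' lesions, within white matter, excluding the infarct zone), assigns the
#' latent penumbra free-water field, converts each penumbra voxel with
#' probability `plogis(a + b * FW)` (increasing in baseline free water),
#' schedules each converting voxel's conversion time uniformly among the
#' follow-up visits, and installs the longitudinal FLAIR/FW slopes in
#' converted voxels.
#'
#' With `config$calibrate_growth = TRUE` (default) the logit and the latent
#' FW location are solved per subject so that the expected converted volume
#' matches `target_growth_ml` per year and the class-conditional FW means
#' match the configured penumbra-class means.
#'
#' @param truth a `ground_truth` from [make_anatomy()].
#' @param config the same [cohort_config()].
#' @return the `ground_truth` with `wmh_mask_t`, `progression_mask`,
#'   `conversion_time`, `roi_class`, slope fields and `penumbra_mask`
#'   filled in.
#' @export
grow_lesions <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(truth$wmh_baseline)) stop("baseline mask missing")
  set.seed(derive_seed(config$seed, truth$subject, 2L))
  d <- truth$dim
  tp <- config$timepoints
  wm <- truth$tissue_labels == LBL_WM
  baseline <- truth$wmh_baseline

  pen <- build_penumbra(list(baseline), baseline, wm,
                        truth$infarct_mask,
                        penumbra_config(radius_mm = config$penumbra_radius_mm),
                        voxel_size = truth$voxel_size)
  idx <- which(pen)
  n_pen <- length(idx)

  conv <- logical(n_pen)
  growth <- NULL
  if (n_pen > 0) {
    years <- max(tp) - min(tp)
    n_target <- config$target_growth_ml * years / voxel_ml(config)
    u <- smooth_field(d, config$jitter_fwhm_vox)[idx]
    u <- (u - mean(u)) / sd(u)
    if (config$calibrate_growth) {
      q <- n_target / n_pen
      if (q >= 1) {
        warning("growth target exceeds penumbra volume; all penumbra converts")
        q <- 1 - 1e-6
      }
      growth <- calibrate_growth_logit(
        u, config$fw_jitter_penumbra, q,
        config$roi_fw_means[["pen_prog"]], config$roi_fw_means[["pen_stable"]],
        config$growth_logit)
    } else {
      growth <- list(mu = config$roi_fw_means[["pen_stable"]],
                     a = config$growth_logit[1], b = config$growth_logit[2],
                     residual = NA_real_)
    }
    f_pen <- pmin(pmax(growth$mu + config$fw_jitter_penumbra * u, 0.02), 0.98)
    truth$fw_field[idx] <- f_pen
    w <- plogis(growth$a + growth$b * f_pen)
    if (all(w >= 1 - 1e-12))
      warning("conversion probability is 1 everywhere in the penumbra ",
              "(degenerate growth model: all penumbra converts)")
    conv <- runif(n_pen) < w
  }

  conv_idx <- idx[conv]
  progression <- array(FALSE, d)
  progression[conv_idx] <- TRUE

  ## Conversion time: uniform among follow-up visits (no within-year
  ## dynamics are modelled).
  conv_time <- array(NA_real_, d)
  if (length(conv_idx))
    conv_time[conv_idx] <- sample(tp[-1], length(conv_idx), replace = TRUE)

  wmh_mask_t <- lapply(tp, function(t) {
    m <- baseline
    m[which(!is.na(conv_time) & conv_time <= t)] <- TRUE
    m
  })
  names(wmh_mask_t) <- paste0("t", seq_along(tp))

  ## The measured penumbra is defined from the union of lesions across
  ## time (dilate union, subtract baseline), which extends past the
  ## baseline-dilated risk shell wherever lesions grew. Outer shell voxels
  ## never convert, but they belong to the stable-penumbra class, so they
  ## receive the stable-class free-water distribution.
  pen_meas <- build_penumbra(wmh_mask_t, baseline, wm, truth$infarct_mask,
                             penumbra_config(radius_mm = config$penumbra_radius_mm),
                             voxel_size = truth$voxel_size)
  outer <- which(pen_meas & !pen)
  if (length(outer) && !is.null(growth)) {
    u_out <- smooth_field(d, config$jitter_fwhm_vox)[outer]
    u_out <- (u_out - mean(u_out)) / max(sd(u_out), 1e-12)
    truth$fw_field[outer] <- pmin(pmax(
      config$roi_fw_means[["pen_stable"]] +
        config$fw_jitter_penumbra * u_out, 0.02), 0.98)
  }
  pen_all <- pen | pen_meas

  roi <- truth$roi_class
  roi[pen_all] <- ROI_PEN_STABLE
  roi[progression] <- ROI_PEN_PROG

  flair_mean <- array(0, d)
  for (k in seq_along(.roi_levels))
    flair_mean[roi == k] <- config$roi_flair_means[[.roi_levels[k]]]

  flair_slope <- array(0, d)
  flair_slope[progression] <- config$flair_slope_progressing
  fw_slope <- array(0, d)
  fw_slope[progression] <- config$fw_slope_progressing

  ## progressing penumbra voxels keep their calibrated FW but the tensor
  ## field follows the final ROI class means (plus the within-class jitter
  ## drawn in make_anatomy)
  truth$tensor_d6 <- build_tensor_field(roi, config, truth$fa_jitter,
                                        truth$md_jitter)

  truth$wmh_mask_t <- wmh_mask_t
  truth$progression_mask <- progression
  truth$conversion_time <- conv_time
  truth$roi_class <- roi
  truth$flair_mean_field <- flair_mean
  truth$flair_slope_field <- flair_slope
  truth$fw_slope_field <- fw_slope
  truth$penumbra_mask <- pen_all
  truth$risk_shell <- pen
  truth$growth_params <- growth
  truth
}

#' Segmentation masks as seen by downstream stages
#'
#' Returns the true lesion masks, optionally corrupted by flipping boundary
#' voxels at `config$label_flip_rate` to emulate automated-segmentation
#' error.
#'
#' @param truth grown `ground_truth`.
#' @param config the [cohort_config()].
#' @return list of per-timepoint logical lesion masks.
#' @export
segmentation_masks <- function(truth, config) {
  masks <- truth$wmh_mask_t
  rate <- config$label_flip_rate
  if (rate <= 0) return(masks)
  set.seed(derive_seed(config$seed, truth$subject, 3L))
  offs <- connectivity_offsets(6)
  lapply(masks, function(m) {
    nb <- array(0L, dim(m))
    for (i in seq_len(nrow(offs)))
      nb <- nb + shift_array(m * 1L, offs[i, ], fill = 0L)
    boundary <- (m & nb < 6L) | (!m & nb > 0L)
    flip <- boundary & array(runif(length(m)) < rate, dim(m))
    out <- xor(m, flip)
    out & (truth$tissue_labels == LBL_WM)
  })
}
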
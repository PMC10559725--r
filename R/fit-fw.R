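## Single-shell free-water elimination: per voxel,
##   S_i = S0 [ f e^{-b_i d_fw} + (1-f) e^{-b_i g_i' D g_i} ],
## free-water diffusivity fixed at d_fw = 3.0e-3 mm^2/s.
##
## Two estimation modes are provided:
##
## "profile": the plain least-squares fit. The problem is separable in f:
##   at a candidate f the corrected attenuation is a single-tensor signal,
##   so D follows from a log-linear solve shared across voxels; the
##   residual is profiled over a grid of f and refined parabolically (or by
##   per-voxel golden section). Exact in the noiseless/high-SNR regime.
##
## "anchored": the practical mode for clinical SNR. A single b-shell
##   leaves the likelihood almost flat along the (f, tissue-trace)
##   direction (trading free water against tissue diffusivity changes the
##   signal only through a high-order nonlinearity), so an unregularized
##   fit is degenerate on noisy data. Following the single-shell free-water
##   literature, the fit is anchored by a tissue-diffusivity constraint:
##   the tissue trace is tied to a linear FW-MD coupling line
##   (md_tissue = md0 + k_md * f, defaults from published white matter
##   values), f is solved by projecting the measured attenuation onto the
##   line segment between the free-water and model tissue attenuations
##   (linear in the data, hence nearly unbiased), and the tensor is
##   re-estimated at the converged f with a weighted log-linear pass.

#' Options for the single-shell free-water fit
#'
#' @param method `"profile"` (plain least squares; exact for noiseless
#'   data) or `"anchored"` (tissue-trace-anchored fit for noisy clinical
#'   SNR data; see Details in [fit_freewater_singleshell()]).
#' @param f_grid candidate free-water fractions for the profile search.
#' @param refine `"parabolic"` (default), `"optimize"` (adds a per-voxel
#'   1-D golden-section pass, slower) or `"none"`; profile mode only.
#' @param f_init optional per-voxel initialization (vector over the mask or
#'   3D array); restricts the profile search to `f_init +- init_halfwidth`.
#' @param init_halfwidth half-width of the restricted search.
#' @param md_tissue_ref reference tissue mean diffusivity (mm^2/s) for the
#'   reported MD-heuristic starting fraction
#'   `f0 = clip((MD_wls - md_ref)/(d_fw - md_ref), 0.01, 0.99)`.
#' @param md_coupling `c(md0, k_md)` of the anchored mode's tissue-trace
#'   line `md_tissue = md0 + k_md * f` (mm^2/s); defaults are the least
#'   squares line through published white matter (FW, MD_Tissue) class
#'   means.
#' @param md_bounds allowed tissue MD range for the anchor (mm^2/s).
#' @param max_iter anchored-mode fixed-point iteration cap.
#' @param tol anchored-mode convergence tolerance on f.
#' @param rel_tol tolerance of the `optimize` refinement.
#' @return list of options.
#' @export
fw_fit_options <- function(method = c("profile", "anchored"),
                           f_grid = seq(0, 0.98, by = 0.02),
                           refine = c("parabolic", "optimize", "none"),
                           f_init = NULL, init_halfwidth = 0.1,
                           md_tissue_ref = 0.6e-3,
                           md_coupling = c(5.527e-4, 2.723e-4),
                           md_bounds = c(4e-4, 1.3e-3),
                           max_iter = 60, tol = 1e-8, rel_tol = 1e-10) {
  list(method = match.arg(method), f_grid = f_grid,
       refine = match.arg(refine), f_init = f_init,
       init_halfwidth = init_halfwidth, md_tissue_ref = md_tissue_ref,
       md_coupling = md_coupling, md_bounds = md_bounds,
       max_iter = max_iter, tol = tol, rel_tol = rel_tol)
}

## Residual sum of squares and tensor for ONE candidate f across all voxels.
.fw_profile_step <- function(att, f, ew_fw, bvals, Xd, proj, floor_eps = 1e-8) {
  corr <- (att - matrix(f * ew_fw, nrow(att), length(ew_fw), byrow = TRUE)) /
    (1 - f)
  bad <- corr < floor_eps
  corr[bad] <- floor_eps
  d6 <- log(corr) %*% proj
  pred_t <- exp(-(d6 %*% t(Xd)) *
                  matrix(bvals, nrow(att), length(bvals), byrow = TRUE))
  pred <- f * matrix(ew_fw, nrow(att), length(ew_fw), byrow = TRUE) +
    (1 - f) * pred_t
  rss <- rowSums((att - pred)^2) + rowSums(bad) * 1e-6
  list(rss = rss, d6 = d6)
}

## Weighted log-linear tensor solve (weights = squared corrected
## attenuation, the classic WLS scheme); per-voxel 6x6 normal equations via
## the pairwise column-product trick.
.wls_tensor <- function(corr, Xb) {
  Y <- log(corr)
  W <- corr^2
  pairs <- which(upper.tri(matrix(0, 6, 6), diag = TRUE), arr.ind = TRUE)
  P <- Xb[, pairs[, 1]] * Xb[, pairs[, 2]]
  XtWX <- W %*% P
  XtWy <- (W * Y) %*% Xb
  n <- nrow(corr)
  d6 <- matrix(0, n, 6)
  A <- matrix(0, 6, 6)
  ut <- upper.tri(A, diag = TRUE)
  lt <- lower.tri(A)
  for (v in seq_len(n)) {
    A[ut] <- XtWX[v, ]
    A[lt] <- t(A)[lt]
    d6[v, ] <- tryCatch(solve(A, XtWy[v, ]),
                        error = function(e) rep(NA_real_, 6))
  }
  bad <- !is.finite(d6[, 1])
  if (any(bad)) d6[bad, ] <- (Y %*% MASS_ginv_cache(Xb))[bad, , drop = FALSE]
  d6
}

## cached unweighted projector (fallback for singular WLS voxels)
MASS_ginv_cache <- local({
  cache <- NULL; xb <- NULL
  function(Xb) {
    if (is.null(cache) || !identical(dim(xb), dim(Xb)) || !all(xb == Xb)) {
      cache <<- t(solve(crossprod(Xb), t(Xb))); xb <<- Xb
    }
    t(cache)
  }
})

.fw_fit_profile <- function(att, usable, bvals, ew_fw, Xd, proj, opts, n) {
  fg <- sort(unique(pmin(pmax(opts$f_grid, 0), 0.995)))
  f_init <- opts$f_init
  rssm <- matrix(Inf, n, length(fg))
  tensors <- vector("list", length(fg))
  for (j in seq_along(fg)) {
    st <- .fw_profile_step(att, fg[j], ew_fw, bvals, Xd, proj)
    rssm[, j] <- st$rss
    tensors[[j]] <- st$d6
  }
  if (!is.null(f_init)) {
    lo <- pmin(pmax(f_init - opts$init_halfwidth, 0), 0.995)
    hi <- pmin(pmax(f_init + opts$init_halfwidth, 0), 0.995)
    fmat <- matrix(fg, n, length(fg), byrow = TRUE)
    rssm[fmat < lo | fmat > hi] <- Inf
  }
  jbest <- max.col(-rssm, ties.method = "first")
  fbest <- fg[jbest]
  d6 <- matrix(0, n, 6)
  for (j in seq_along(fg)) {
    vi <- which(jbest == j)
    if (length(vi)) d6[vi, ] <- tensors[[j]][vi, , drop = FALSE]
  }
  rss <- rssm[cbind(seq_len(n), jbest)]

  if (opts$refine %in% c("parabolic", "optimize") && length(fg) >= 3L) {
    jm <- pmin(pmax(jbest, 2L), length(fg) - 1L)
    r0 <- rssm[cbind(seq_len(n), jm - 1L)]
    r1 <- rssm[cbind(seq_len(n), jm)]
    r2 <- rssm[cbind(seq_len(n), jm + 1L)]
    denom <- r0 - 2 * r1 + r2
    ok <- is.finite(r0) & is.finite(r2) & denom > 0
    step <- fg[jm + 1L] - fg[jm]
    adj <- ifelse(ok, 0.5 * (r0 - r2) / denom * step, 0)
    fpar <- pmin(pmax(fg[jm] + adj, fg[1]), fg[length(fg)])
    fbest <- ifelse(jbest > 1L & jbest < length(fg), fpar, fbest)
  }

  refit <- function(v, f)
    .fw_profile_step(att[v, , drop = FALSE], f, ew_fw, bvals, Xd, proj)
  if (opts$refine == "optimize") {
    for (v in which(usable)) {
      lo_v <- if (is.null(f_init)) max(fbest[v] - 0.05, 0) else
        max(f_init[v] - opts$init_halfwidth, 0)
      hi_v <- if (is.null(f_init)) min(fbest[v] + 0.05, 0.995) else
        min(f_init[v] + opts$init_halfwidth, 0.995)
      op <- optimize(function(f) refit(v, f)$rss, c(lo_v, hi_v),
                     tol = opts$rel_tol)
      if (op$objective <= rss[v] + 1e-15) {
        fbest[v] <- op$minimum
        rss[v] <- op$objective
      }
    }
  }
  if (opts$refine != "none") {
    changed <- which(usable & abs(fbest - fg[jbest]) > 1e-12)
    for (v in changed) {
      st <- refit(v, fbest[v])
      d6[v, ] <- st$d6
      rss[v] <- st$rss
    }
  }
  list(f = fbest, d6 = d6, rss = rss, converged = rep(TRUE, n),
       check_pure = TRUE)
}

.fw_fit_anchored <- function(att, usable, bvals, ew_fw, Xd, proj, opts, n) {
  nd <- length(bvals)
  ewm <- matrix(ew_fw, n, nd, byrow = TRUE)
  f <- rep(0.3, n)
  corr <- pmax((att - f * ewm) / (1 - f), 1e-8)
  d6 <- log(corr) %*% proj
  md0 <- opts$md_coupling[1]
  kmd <- opts$md_coupling[2]
  converged <- rep(FALSE, n)
  for (it in seq_len(opts$max_iter)) {
    md_model <- pmin(pmax(md0 + kmd * f, opts$md_bounds[1]),
                     opts$md_bounds[2])
    md_cur <- pmax((d6[, 1] + d6[, 2] + d6[, 3]) / 3, 1e-5)
    d6s <- d6 * (md_model / md_cur)
    At <- exp(-(d6s %*% t(Xd)) * matrix(bvals, n, nd, byrow = TRUE))
    fn <- pmin(pmax(rowSums((att - At) * (ewm - At)) /
                      pmax(rowSums((ewm - At)^2), 1e-12), 0), 0.99)
    delta <- abs(fn - f)
    f <- fn
    corr <- pmax((att - f * ewm) / (1 - f), 1e-8)
    d6 <- log(corr) %*% proj
    if (max(delta[usable], 0) < opts$tol) {
      converged <- rep(TRUE, n)
      break
    }
  }
  ## weighted final tensor pass (reduces the log-fit noise bias on FA/MD)
  d6 <- .wls_tensor(corr, -bvals * Xd)
  pred <- f * ewm + (1 - f) *
    exp(-(d6 %*% t(Xd)) * matrix(bvals, n, nd, byrow = TRUE))
  list(f = f, d6 = d6, rss = rowSums((att - pred)^2),
       converged = converged, check_pure = FALSE)
}

#' Fit the single-shell free-water (bi-tensor) model
#'
#' Per-voxel estimates of the free-water fraction `f`, the tissue tensor
#' and its FW-corrected scalars (FA_Tissue, MD_Tissue). `S0` is taken as
#' the mean of the b = 0 volumes. Voxels whose signals are all (near) zero
#' are marked unfit and excluded from the maps.
#'
#' Two modes (see [fw_fit_options()]): `"profile"` is the plain
#' least-squares estimator, exact on noiseless data but degenerate at
#' clinical SNR because a single shell barely distinguishes free water
#' from a faster tissue trace; `"anchored"` resolves that degeneracy with
#' a tissue-trace coupling anchor and is the mode the pipeline uses on
#' noisy data.
#'
#' @param dwi 4D array `(x, y, z, volume)` or n x nvol signal matrix.
#' @param scheme an [acquisition_scheme()].
#' @param mask logical 3D array of voxels to fit (4D input only).
#' @param opts an [fw_fit_options()] list.
#' @param d_fw free-water diffusivity, mm^2/s (body-temperature CSF).
#' @return object of class `freewater_fit`: per-voxel vectors `f`,
#'   `fa_tissue`, `md_tissue`, `s0`, `rmse`, `converged`, `f0_init`; the
#'   tissue `tensor` (n x 6); `n_clamped`, `n_unfit`; and `idx`/`dim` for
#'   [fit_map()].
#' @export
fit_freewater_singleshell <- function(dwi, scheme, mask = NULL,
                                      opts = fw_fit_options(), d_fw = D_FW) {
  sm <- as_signal_matrix(dwi, mask)
  sig <- sm$sig
  nvol <- length(scheme$bvals)
  if (ncol(sig) != nvol) stop("signal count does not match scheme")
  b0 <- scheme$b0
  s0 <- rowMeans(sig[, b0, drop = FALSE])
  usable <- is.finite(s0) & s0 > 0 & rowSums(sig > 0) >= 7L
  n <- nrow(sig)

  dw <- !b0
  bvals <- scheme$bvals[dw]
  ew_fw <- exp(-bvals * d_fw)
  Xd <- tensor_design(scheme$bvecs[, dw, drop = FALSE])
  Xb <- -bvals * Xd
  proj <- t(solve(crossprod(Xb), t(Xb)))

  att <- sig[, dw, drop = FALSE] / ifelse(s0 > 0, s0, 1)
  att[!usable, ] <- 1

  wls <- fit_dti_wls(sig, scheme)
  f0 <- pmin(pmax((wls$md - opts$md_tissue_ref) /
                    (d_fw - opts$md_tissue_ref), 0.01), 0.99)

  f_init <- opts$f_init
  if (!is.null(f_init) && !is.null(dim(f_init)))
    opts$f_init <- f_init[sm$idx]

  fit <- if (opts$method == "anchored")
    .fw_fit_anchored(att, usable, bvals, ew_fw, Xd, proj, opts, n)
  else
    .fw_fit_profile(att, usable, bvals, ew_fw, Xd, proj, opts, n)

  fbest <- fit$f
  d6 <- fit$d6
  rss <- fit$rss
  sc <- tensor_scalars(d6)
  fa <- sc$fa
  md <- sc$md

  if (isTRUE(fit$check_pure)) {
    ## pure free-water check: does f = 1 (no tissue) match the bi-tensor
    ## optimum? Ties go to f = 1: pure free water is unidentifiable in f
    ## when the fitted "tissue" tensor equals the free-water tensor.
    rss_fw1 <- rowSums((att - matrix(ew_fw, n, length(ew_fw),
                                     byrow = TRUE))^2)
    pure <- usable & rss_fw1 <= rss + 1e-12
    fbest[pure] <- 1
    fa[pure] <- 0
    md[pure] <- 0
    d6[pure, ] <- 0
    rss[pure] <- rss_fw1[pure]
  }

  rmse <- sqrt(pmax(rss, 0) / sum(dw)) * s0
  structure(list(
    f = ifelse(usable, fbest, NA_real_),
    tensor = d6,
    fa_tissue = ifelse(usable, pmin(pmax(fa, 0), 1), NA_real_),
    md_tissue = ifelse(usable, pmax(md, 0), NA_real_),
    s0 = s0, rmse = ifelse(usable, rmse, NA_real_),
    converged = fit$converged & usable, f0_init = f0,
    n_clamped = sc$n_clamped, n_unfit = sum(!usable),
    idx = sm$idx, dim = sm$dim), class = "freewater_fit")
}

#' Expand a fitted per-voxel vector into a 3D map
#'
#' @param fit a `freewater_fit` (or any list with `idx` and `dim`).
#' @param what name of the per-voxel field (e.g. `"f"`, `"fa_tissue"`).
#' @param fill background value.
#' @return 3D array.
#' @export
fit_map <- function(fit, what = "f", fill = NA_real_) {
  if (is.null(fit$dim)) stop("fit was computed from a matrix; no grid known")
  out <- array(fill, fit$dim)
  out[fit$idx] <- fit[[what]]
  out
}
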
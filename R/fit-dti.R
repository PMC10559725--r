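## Conventional diffusion tensor fitting (log-linear weighted least
## squares) and the trace image. Signals are passed as an n x nvol matrix
## (one row per voxel) or a 4D array.

as_signal_matrix <- function(dwi, mask = NULL) {
  if (is.matrix(dwi)) {
    list(sig = dwi, idx = seq_len(nrow(dwi)), dim = NULL)
  } else {
    d <- dim(dwi)
    stopifnot(length(d) == 4L)
    flat <- matrix(dwi, prod(d[1:3]), d[4])
    idx <- if (is.null(mask)) seq_len(nrow(flat)) else which(mask)
    list(sig = flat[idx, , drop = FALSE], idx = idx, dim = d[1:3])
  }
}

#' Weighted least-squares diffusion tensor fit
#'
#' Log-linear fit of `log S = log S0 - b g'Dg` per voxel: an OLS pass in
#' log-signal space followed by one reweighted pass with weights equal to
#' the squared predicted signals (the standard WLS scheme). Signals are
#' floored at a small epsilon before taking logs.
#'
#' @param dwi 4D array `(x, y, z, volume)` or n x nvol signal matrix.
#' @param scheme an [acquisition_scheme()].
#' @param mask logical 3D array of voxels to fit (4D input only).
#' @param floor_eps positive signal floor.
#' @return list with `tensor` (n x 6), `s0`, `fa`, `md`, `n_clamped` and
#'   `idx` (voxel indices fitted).
#' @export
fit_dti_wls <- function(dwi, scheme, mask = NULL, floor_eps = 1e-6) {
  sm <- as_signal_matrix(dwi, mask)
  sig <- pmax(sm$sig, floor_eps)
  nvol <- length(scheme$bvals)
  if (ncol(sig) != nvol) stop("signal count does not match scheme")
  if (nvol < 7L) stop("need at least 7 measurements per voxel")
  ## design: log S = [1, -b * quadratic-form design] [log S0; d6]
  X <- cbind(1, -scheme$bvals * tensor_design(scheme$bvecs))
  if (qr(X)$rank < 7L)
    stop("singular design: gradient directions are coplanar/degenerate")
  Y <- log(sig)                       # n x nvol
  beta <- Y %*% t(solve(crossprod(X), t(X)))   # OLS, n x 7
  ## one reweighting pass; per-voxel 7x7 normal equations built via the
  ## pairwise column-product trick so the pass stays vectorized
  W <- exp(2 * (beta %*% t(X)))                # predicted signal^2 weights
  pairs <- which(upper.tri(matrix(0, 7, 7), diag = TRUE), arr.ind = TRUE)
  P <- X[, pairs[, 1]] * X[, pairs[, 2]]       # nvol x 28
  XtWX <- W %*% P                              # n x 28
  XtWy <- (W * Y) %*% X                        # n x 7
  n <- nrow(sig)
  A <- matrix(0, 7, 7)
  ut <- upper.tri(A, diag = TRUE)
  for (v in seq_len(n)) {
    A[ut] <- XtWX[v, ]
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    b <- tryCatch(solve(A, XtWy[v, ]), error = function(e) beta[v, ])
    beta[v, ] <- b
  }
  sc <- tensor_scalars(beta[, 2:7, drop = FALSE])
  list(tensor = beta[, 2:7, drop = FALSE], s0 = exp(beta[, 1]),
       fa = sc$fa, md = sc$md, n_clamped = sc$n_clamped, idx = sm$idx,
       dim = sm$dim)
}

#' Trace image: geometric mean of the diffusion-weighted volumes
#'
#' Per voxel, `exp(mean(log(S_i)))` over the b > 0 volumes. Non-positive
#' intensities are floored at `floor_eps` and flagged.
#'
#' @inheritParams fit_dti_wls
#' @return list with `trace` (3D array for 4D input, vector otherwise) and
#'   `n_floored`.
#' @export
compute_trace <- function(dwi, scheme, floor_eps = 1e-6) {
  sm <- as_signal_matrix(dwi, NULL)
  dw <- sm$sig[, !scheme$b0, drop = FALSE]
  if (!ncol(dw)) stop("need at least one b > 0 volume")
  n_floored <- sum(dw < floor_eps)
  dw <- pmax(dw, floor_eps)
  tr <- exp(rowMeans(log(dw)))
  if (!is.null(sm$dim)) tr <- array(tr, sm$dim)
  list(trace = tr, n_floored = n_floored)
}
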
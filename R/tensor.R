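## Symmetric diffusion tensor utilities. Tensors are stored as the six
## unique elements in the order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), mm^2/s;
## per-voxel maps are n x 6 matrices.

## Free-water (CSF-like compartment) diffusivity at body temperature,
## mm^2/s; the universal constant of free-water elimination models.
D_FW <- 3.0e-3

#' Design matrix mapping tensor elements to g' D g quadratic forms
#'
#' Row i is (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz) for direction i,
#' so `design %*% d6` gives the apparent diffusivity along each direction.
#' @keywords internal
tensor_design <- function(bvecs) {
  g <- t(bvecs)
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

## Analytic eigenvalues of symmetric 3x3 tensors, vectorized over rows of an
## n x 6 matrix. Returns n x 3 matrix, eigenvalues in decreasing order.
tensor_eigenvalues <- function(d6) {
  d6 <- rbind(d6)
  q <- (d6[, 1] + d6[, 2] + d6[, 3]) / 3
  p1 <- d6[, 4]^2 + d6[, 5]^2 + d6[, 6]^2
  p2 <- (d6[, 1] - q)^2 + (d6[, 2] - q)^2 + (d6[, 3] - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1e-30) * 1e3 | p == 0
  ps <- ifelse(iso, 1, p)
  b11 <- (d6[, 1] - q) / ps; b22 <- (d6[, 2] - q) / ps; b33 <- (d6[, 3] - q) / ps
  b12 <- d6[, 4] / ps; b13 <- d6[, 5] / ps; b23 <- d6[, 6] / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, ] <- q[iso]
  out
}

#' Fractional anisotropy and mean diffusivity of diffusion tensors
#'
#' Eigenvalues are computed analytically and clamped at zero (non-negative
#' diffusivities); the number of voxels needing clamping is reported.
#' A degenerate all-zero tensor has FA defined as 0.
#'
#' @param d6 n x 6 tensor element matrix (or length-6 vector), order
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @return list with `fa`, `md`, `eigenvalues` (n x 3, clamped) and
#'   `n_clamped`.
#' @export
tensor_scalars <- function(d6) {
  ev <- tensor_eigenvalues(d6)
  n_clamped <- sum(apply(ev < 0, 1L, any))
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  list(fa = as.numeric(fa), md = as.numeric(md), eigenvalues = ev,
       n_clamped = n_clamped)
}

#' Build an axially symmetric tensor with prescribed FA and MD
#'
#' Eigenvalues are (MD(1+2*delta), MD(1-delta), MD(1-delta)) with delta
#' solved from FA; the first eigenvector is `axis`.
#'
#' @param fa fractional anisotropy in `[0, 1)`.
#' @param md mean diffusivity, mm^2/s.
#' @param axis principal axis (any nonzero 3-vector; defaults to x).
#' @return length-6 tensor element vector.
#' @export
tensor_from_fa_md <- function(fa, md, axis = c(1, 0, 0)) {
  stopifnot(fa >= 0, fa < 1, md >= 0)
  delta <- fa * sqrt(3 / (9 - 6 * fa^2))
  l1 <- md * (1 + 2 * delta)
  l2 <- md * (1 - delta)
  v <- axis / sqrt(sum(axis^2))
  ## D = l2 I + (l1 - l2) v v'
  D <- diag(rep(l2, 3)) + (l1 - l2) * tcrossprod(v)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Two-compartment (free-water elimination) diffusion forward model
#'
#' `S(b, g) = S0 * (f * exp(-b * d_fw) + (1 - f) * exp(-b * g' D g))`,
#' with fixed free-water diffusivity `d_fw`.
#'
#' @param s0 non-diffusion-weighted signal (scalar or length-n).
#' @param f free-water fraction in `[0, 1]` (scalar or length-n).
#' @param d6 tissue tensor elements, n x 6 matrix or length-6 vector.
#' @param scheme an [acquisition_scheme()].
#' @param d_fw free-water diffusivity, mm^2/s.
#' @return n x nvol signal matrix (n = number of voxels).
#' @export
bitensor_signal <- function(s0, f, d6, scheme, d_fw = D_FW) {
  d6 <- rbind(d6)
  dimnames(d6) <- NULL
  n <- nrow(d6)
  s0 <- rep(s0, length.out = n)
  f <- rep(f, length.out = n)
  stopifnot(all(f >= 0 & f <= 1))
  X <- tensor_design(scheme$bvecs)          # nvol x 6
  adc <- d6 %*% t(X)                        # n x nvol, g' D g
  b <- matrix(scheme$bvals, n, length(scheme$bvals), byrow = TRUE)
  s0 * (f * exp(-b * d_fw) + (1 - f) * exp(-b * adc))
}

#' Add MRI noise to a signal matrix
#'
#' Rician noise (`sqrt((S + n1)^2 + n2^2)`, magnitude reconstruction) or
#' additive Gaussian noise.
#'
#' @param signal numeric matrix/array of noiseless signals.
#' @param sd noise standard deviation per channel; `0` returns the input.
#' @param model `"rician"` or `"gaussian"`.
#' @return noisy signals (Rician: strictly non-negative).
#' @export
add_noise <- function(signal, sd, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (sd <= 0) return(signal)
  n <- length(signal)
  if (model == "rician") {
    re <- signal + rnorm(n, sd = sd)
    im <- rnorm(n, sd = sd)
    out <- sqrt(re^2 + im^2)
  } else {
    out <- signal + rnorm(n, sd = sd)
  }
  dim(out) <- dim(signal)
  out
}
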
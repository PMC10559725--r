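## Low-level 3D array helpers shared by the simulator, the denoiser and the
## cluster machinery. All operate on plain 3D numeric/logical arrays.

#' Shift a 3D array by an integer voxel offset
#'
#' Voxels shifted in from outside the grid are filled with `fill`.
#'
#' @param a 3D array.
#' @param offset integer length-3 offset (voxels). `c(1,0,0)` moves content
#'   towards increasing x, i.e. `out[i,,] == a[i-1,,]`.
#' @param fill fill value for exposed voxels.
#' @return shifted array, same dimensions.
#' @keywords internal
shift_array <- function(a, offset, fill = 0) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(offset) == 3L)
  offset <- as.integer(offset)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- offset[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq_len(d[k] - o) + o
    } else {
      src[[k]] <- seq_len(d[k] + o) - o
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Running (moving) sum of length 2r+1 along the first axis of a matrix,
## zero-padded at the ends; vectorized over columns via cumsum.
run_sum_1d <- function(m, r) {
  if (r == 0L) return(m)
  n <- nrow(m)
  cs <- apply(rbind(0, m), 2L, cumsum)
  hi <- pmin(seq_len(n) + r, n) + 1L
  lo <- pmax(seq_len(n) - r, 0L) + 1L
  cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
}

## Apply a 1D operation along axis `axis` of a 3D array by permuting that
## axis to the front and flattening the other two into columns.
apply_along_axis <- function(a, axis, fun) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- fun(m)
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

#' Box-filter sum over a cubic neighbourhood
#'
#' Sum of `a` over the (2r+1)^3 cube centred at each voxel (zero padding),
#' computed separably.
#' @keywords internal
box_sum <- function(a, r) {
  for (ax in 1:3) a <- apply_along_axis(a, ax, function(m) run_sum_1d(m, r))
  a
}

## 1D convolution of matrix columns with kernel k (odd length), zero padded.
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    o <- j - r - 1L             # offset applied to row index
    ii <- seq_len(n)
    src <- ii - o
    ok <- src >= 1L & src <= n
    out[ii[ok], ] <- out[ii[ok], ] + k[j] * m[src[ok], , drop = FALSE]
  }
  out
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param a 3D array.
#' @param fwhm full width at half maximum of the kernel, in voxels; scalar
#'   or per-axis length-3.
#' @param normalize if `TRUE`, divide by the smoothed all-ones volume so
#'   edge voxels are renormalized (kernel mass inside the grid sums to 1).
#' @return smoothed array.
#' @export
gauss_smooth <- function(a, fwhm, normalize = TRUE) {
  fwhm <- rep(fwhm, length.out = 3L)
  sm <- function(x) {
    for (ax in 1:3) {
      sigma <- fwhm[ax] / sqrt(8 * log(2))
      if (sigma <= 0) next
      half <- max(1L, ceiling(4 * sigma))
      k <- stats::dnorm(seq(-half, half), sd = sigma)
      k <- k / sum(k)
      x <- apply_along_axis(x, ax, function(m) conv_cols(m, k))
    }
    x
  }
  out <- sm(a)
  if (normalize) {
    w <- sm(array(1, dim(a)))
    out <- out / w
  }
  out
}

#' Neighbourhood offsets for a given connectivity
#'
#' @param connectivity 6, 18 or 26.
#' @return integer matrix, one offset per row.
#' @keywords internal
connectivity_offsets <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' Breadth-first labelling under 6/18/26-connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26, the common neuroimaging
#'   cluster rule).
#' @return list with `labels` (integer array, 0 = background), `n` (number
#'   of components) and `sizes` (voxels per component).
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(list(labels = labels, n = 0L, sizes = integer(0)))
  inmask <- mask
  next_lab <- 0L
  sizes <- integer(0)
  for (seed in idx) {
    if (labels[seed] != 0L) next
    next_lab <- next_lab + 1L
    frontier <- arrayInd(seed, d)
    labels[seed] <- next_lab
    count <- 1L
    while (nrow(frontier)) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
            cand[, 2] >= 1L & cand[, 2] <= d[2] &
            cand[, 3] >= 1L & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique((cand[, 3] - 1L) * (d[1] * d[2]) + (cand[, 2] - 1L) * d[1] + cand[, 1])
      lin <- lin[inmask[lin] & labels[lin] == 0L]
      if (!length(lin)) break
      labels[lin] <- next_lab
      count <- count + length(lin)
      frontier <- arrayInd(lin, d)
    }
    sizes[next_lab] <- count
  }
  list(labels = labels, n = next_lab, sizes = sizes)
}

#' Voxel offsets within a physical radius
#'
#' All nonzero integer offsets whose centre-to-centre Euclidean distance,
#' under (possibly anisotropic) voxel sizes in mm, is at most `radius_mm`.
#'
#' @param radius_mm dilation radius in mm.
#' @param voxel_size mm per axis (length 3).
#' @return integer offset matrix (n x 3).
#' @keywords internal
mm_ball_offsets <- function(radius_mm, voxel_size) {
  stopifnot(radius_mm > 0, length(voxel_size) == 3L, all(voxel_size > 0))
  rmax <- floor(radius_mm / voxel_size)
  g <- as.matrix(expand.grid(dx = -rmax[1]:rmax[1],
                             dy = -rmax[2]:rmax[2],
                             dz = -rmax[3]:rmax[3]))
  dist <- sqrt((g[, 1] * voxel_size[1])^2 +
               (g[, 2] * voxel_size[2])^2 +
               (g[, 3] * voxel_size[3])^2)
  g[dist <= radius_mm & dist > 0, , drop = FALSE]
}

#' Morphological dilation by a physical (mm) radius
#'
#' A voxel is in the dilated mask iff its centre lies within `radius_mm`
#' (Euclidean, honouring anisotropic voxel sizes) of the centre of any mask
#' voxel. The input mask itself is always included.
#'
#' @param mask logical 3D array.
#' @param radius_mm radius in mm.
#' @param voxel_size mm per axis.
#' @return logical array.
#' @export
dilate_mm <- function(mask, radius_mm, voxel_size) {
  offs <- mm_ball_offsets(radius_mm, voxel_size)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_array(mask, offs[i, ], fill = FALSE)
  }
  out
}
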
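## Diffusion acquisition scheme: b-values (s/mm^2) and unit gradient
## directions. bvecs follow the FSL dialect: 3 rows x N columns.

#' Construct a single-shell diffusion acquisition scheme
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs 3 x N matrix of gradient directions (FSL dialect: one column
#'   per volume). Directions for b > 0 volumes must be unit length within
#'   1e-6; b = 0 columns may be zero.
#' @param min_directions minimum number of unique (up to sign) gradient
#'   directions. Tensor fitting needs 6; schemes intended only for signal
#'   synthesis or trace images may lower this.
#' @return object of class `acquisition_scheme` with elements `bvals`,
#'   `bvecs`, `b0` (logical index of b = 0 volumes) and `bshell` (the shared
#'   nonzero b-value).
#' @export
acquisition_scheme <- function(bvals, bvecs, min_directions = 6L) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop("bvecs must be a 3 x length(bvals) matrix (FSL dialect)")
  b0 <- bvals <= 0
  if (!any(b0)) stop("scheme must contain at least one b = 0 volume")
  shell <- unique(bvals[!b0])
  if (length(shell) != 1L)
    stop("all nonzero b-values must be equal (single shell); got: ",
         paste(shell, collapse = ", "))
  nrm <- sqrt(colSums(bvecs[, !b0, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("gradient directions for b > 0 volumes must be unit vectors")
  ## count directions unique up to sign (antipodal pairs measure the same
  ## diffusion attenuation)
  g <- bvecs[, !b0, drop = FALSE]
  g <- apply(g, 2L, function(v) if (v[which.max(abs(v))] < 0) -v else v)
  ndir <- nrow(unique(round(t(g), 6)))
  if (ndir < min_directions)
    stop("need at least ", min_directions,
         " unique gradient directions; got ", ndir)
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0, bshell = shell,
                 n_directions = ndir),
            class = "acquisition_scheme")
}

## 12 electrostatically-distributed unit directions (antipodally optimized),
## frozen so that default cohorts are reproducible across platforms.
.dirs12 <- matrix(c(
   0.072707,  0.993132, 0.091669,
  -0.603825,  0.152136, 0.782464,
   0.061434, -0.816544, 0.574005,
   0.855874,  0.184829, 0.483029,
   0.036572, -0.091456, 0.995137,
   0.703954, -0.708602, 0.048294,
   0.607428, -0.397775, 0.687609,
  -0.575520, -0.526802, 0.625505,
  -0.981916,  0.056815, 0.180593,
   0.709664,  0.703394, 0.040179,
  -0.355359,  0.734719, 0.577848,
   0.314528,  0.560324, 0.766231), ncol = 3, byrow = TRUE)

#' Default acquisition scheme: 4 b=0 volumes + 12 directions at b=1000
#'
#' Mirrors a common clinical single-shell DTI protocol (12 directional
#' images at b = 1000 s/mm^2 plus 4 b = 0 images).
#'
#' @param bshell shell b-value in s/mm^2.
#' @param n_b0 number of b = 0 volumes.
#' @return an [acquisition_scheme()].
#' @export
default_scheme <- function(bshell = 1000, n_b0 = 4) {
  g <- t(.dirs12)
  g <- g / rep(sqrt(colSums(g^2)), each = 3)
  bvecs <- cbind(matrix(0, 3, n_b0), g)
  bvals <- c(rep(0, n_b0), rep(bshell, ncol(g)))
  acquisition_scheme(bvals, bvecs)
}

#' Read / write FSL-dialect bval and bvec files
#'
#' `.bval` is one row of b-values; `.bvec` is three rows (x, y, z) of
#' gradient components, whitespace separated.
#'
#' @param bval_path,bvec_path file paths.
#' @return an [acquisition_scheme()].
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  dimnames(bvecs) <- NULL
  acquisition_scheme(bvals, bvecs)
}

#' @rdname read_bvalbvec
#' @param scheme an [acquisition_scheme()].
#' @param digits printed precision.
#' @export
write_bvalbvec <- function(scheme, bval_path, bvec_path, digits = 6) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(round(scheme$bvecs, digits), 1L,
                   function(r) paste(format(r, trim = TRUE), collapse = " ")),
             bvec_path)
  invisible(c(bval_path, bvec_path))
}
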
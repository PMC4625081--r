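# Separable 3D Gaussian smoothing used by the cohort simulator.
# FWHM is expressed in voxels so the smoother is geometry-agnostic.

gaussian_kernel_1d <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D array with a normalized 1D kernel along each axis in turn.
# Boundary handling: kernel renormalized over the in-grid support (reflected
# mass would bias edge variance less, but renormalization keeps the smoother
# mean-preserving, which matters for the zero-signal limit).
gauss_smooth3d <- function(vol, fwhm) {
  stopifnot(length(dim(vol)) == 3L)
  if (fwhm <= 0) return(vol)
  k <- gaussian_kernel_1d(fwhm)
  if (length(k) == 1L) return(vol)
  for (ax in 1:3) {
    d <- dim(vol)
    K <- conv_band_matrix(d[1L], k)
    vol <- array(K %*% matrix(vol, nrow = d[1L]), dim = d)
    vol <- aperm(vol, c(2L, 3L, 1L))
  }
  vol
}

# n x n banded convolution matrix for kernel k, rows renormalized at edges.
conv_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

# Smoothed Gaussian white-noise field standardized so that every voxel has
# pointwise standard deviation exactly `sd`. Smoothing white noise shrinks
# pointwise variance by the squared row norm of the convolution operator,
# and edge renormalization makes that shrinkage spatially non-uniform;
# dividing by the exact per-voxel operator sd removes both effects, so the
# `*_sd` config parameters mean what they say at every voxel.
smooth_noise_field <- function(grid_shape, sd, fwhm) {
  if (sd <= 0) return(array(0, dim = grid_shape))
  f <- gauss_smooth3d(array(stats::rnorm(prod(grid_shape)), dim = grid_shape), fwhm)
  f * (sd / smooth_operator_sd(grid_shape, fwhm))
}

# Per-voxel sd of gauss_smooth3d() applied to unit white noise: the separable
# operator's row 2-norms, one factor per axis, combined by outer product.
smooth_operator_sd <- function(grid_shape, fwhm) {
  k <- gaussian_kernel_1d(fwhm)
  if (length(k) == 1L) return(array(1, dim = grid_shape))
  norms <- lapply(grid_shape, function(n)
    sqrt(rowSums(conv_band_matrix(n, k)^2)))
  array(norms[[1L]] %o% norms[[2L]] %o% norms[[3L]], dim = grid_shape)
}
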
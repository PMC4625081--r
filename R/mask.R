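#' Brain mask
#'
#' A binary 3D mask restricting which voxels participate in group statistics
#' and similarity comparisons (standing in for an MNI template brain mask).
#'
#' @param volume logical (or 0/1 numeric) 3D array.
#' @param affine 4x4 voxel-to-world transform; defaults to a 2 mm isotropic
#'   diagonal affine.
#' @return an object of class `brain_mask`.
#' @export
brain_mask <- function(volume, affine = default_affine()) {
  stopifnot(length(dim(volume)) == 3L)
  vol <- array(as.logical(volume), dim = dim(volume))
  if (anyNA(vol)) stop("mask volume must not contain NA")
  if (sum(vol) < 3L) stop("mask must contain at least 3 voxels")
  structure(list(volume = vol, affine = affine), class = "brain_mask")
}

#' Ellipsoidal brain mask
#'
#' Default synthetic "brain": an axis-aligned ellipsoid centred in the grid
#' with semi-axes `semi_frac * grid_shape / 2`.
#'
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param semi_frac fraction of each half-dimension used as the semi-axis.
#' @inheritParams brain_mask
#' @return a [brain_mask()].
#' @export
ellipsoid_mask <- function(grid_shape, semi_frac = 0.84, affine = default_affine()) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3))
  ctr <- (grid_shape + 1) / 2
  semi <- pmax(semi_frac * grid_shape / 2, 1)
  g <- expand.grid(x = seq_len(grid_shape[1L]),
                   y = seq_len(grid_shape[2L]),
                   z = seq_len(grid_shape[3L]))
  d2 <- ((g$x - ctr[1L]) / semi[1L])^2 +
        ((g$y - ctr[2L]) / semi[2L])^2 +
        ((g$z - ctr[3L]) / semi[3L])^2
  brain_mask(array(d2 <= 1, dim = grid_shape), affine = affine)
}

default_affine <- function(voxel_mm = 2) {
  a <- diag(c(rep(voxel_mm, 3), 1))
  a
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<brain_mask> %dx%dx%d grid, %d voxels in mask\n",
              d[1L], d[2L], d[3L], sum(x$volume)))
  invisible(x)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("grid shape mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
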
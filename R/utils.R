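#' @useDynLib nonlocalpls, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pt qnorm quantile rnorm sd t.test var
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a Gaussian full-width-at-half-maximum to a standard deviation
#'
#' @param fwhm Full width at half maximum, in voxel units.
#' @return Standard deviation in voxel units (`fwhm / 2.3548`).
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / 2.3548

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with a separable Gaussian kernel, replicating edge
#' values at the grid boundary (no values are invented outside the grid).
#'
#' @param vol 3D numeric array.
#' @param sigma Gaussian standard deviation in voxels; `0` returns the input.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3L)
  if (sigma <= 0) return(vol)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (i in seq_along(k)) {
      sh <- i - r - 1L
      idx <- pmin(pmax(seq_len(d[axis]) + sh, 1L), d[axis])
      out <- out + k[i] * switch(axis, a[idx, , , drop = FALSE],
                                 a[, idx, , drop = FALSE],
                                 a[, , idx, drop = FALSE])
    }
    out
  }
  conv_axis(conv_axis(conv_axis(vol, 1L), 2L), 3L)
}

# Voxel coordinates are 0-based; arrays are flattened in R's native
# column-major order (first axis fastest). Used everywhere.
flatten_volume <- function(vol, mask = NULL) {
  v <- as.vector(vol)
  if (!is.null(mask)) v[as.vector(mask)] else v
}

unflatten_volume <- function(values, grid_shape, mask = NULL, background = 0) {
  if (is.null(mask)) {
    stopifnot(length(values) == prod(grid_shape))
    return(array(values, dim = grid_shape))
  }
  stopifnot(length(values) == sum(mask))
  out <- array(background, dim = grid_shape)
  out[as.vector(mask)] <- values
  out
}

# 0-based voxel coordinate grid for a given shape: matrix V x 3 in
# column-major order.
voxel_grid <- function(grid_shape) {
  as.matrix(expand.grid(x = seq_len(grid_shape[1]) - 1,
                        y = seq_len(grid_shape[2]) - 1,
                        z = seq_len(grid_shape[3]) - 1))
}

# Deterministic per-repeat seed derivation (kept below 2^31).
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 1000003 * as.numeric(index)) %% 2147483647)
}

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}
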
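# Separable Gaussian smoothing on the lattice, with the exact pointwise
# standard-deviation map of smoothed white noise under the same kernel.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_kernel_1d <- function(fwhm) {
  sigma <- fwhm_to_sigma(fwhm)
  r <- ceiling(4 * sigma)
  d <- seq(-r, r)
  w <- exp(-d^2 / (2 * sigma^2))
  w / sum(w)
}

# Banded convolution matrix for one axis (zero padding: rows near the border
# simply lose out-of-range taps; the kernel is normalised globally, not
# re-normalised per row).
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    j <- seq_len(n) + d
    ok <- j >= 1L & j <= n
    K[cbind(seq_len(n)[ok], j[ok])] <- kernel[d + r + 1L]
  }
  K
}

# Separable convolution over the first `ndim` axes of `arr` (trailing axes,
# e.g. a subject axis, are independent replicates). Applies the kernel to
# the leading axis, then cyclically rotates the spatial axes, so the array
# is permuted only `ndim` times in total and multiplications always hit the
# fast leading-dimension layout.
conv_separable <- function(arr, ndim, kernel) {
  dims <- dim(arr)
  trailing <- seq_along(dims)[-seq_len(ndim)]
  for (a in seq_len(ndim)) {
    d <- dim(arr)
    K <- conv_matrix_1d(d[1L], kernel)
    dim(arr) <- c(d[1L], prod(d[-1L]))
    arr <- K %*% arr
    dim(arr) <- d
    if (ndim > 1L) {
      arr <- aperm(arr, c(seq_len(ndim)[-1L], 1L, trailing))
    }
  }
  arr
}

#' Smooth a lattice field with an isotropic Gaussian kernel
#'
#' Separable convolution with a truncated Gaussian kernel of the given full
#' width at half maximum, `sigma = fwhm / (2 sqrt(2 log 2))`, truncated at
#' radius `ceiling(4 sigma)` and normalised to sum 1. The field is
#' zero-padded: a constant field is unchanged in the interior and attenuated
#' only within the truncation radius of the border. `fwhm = 0` is the
#' identity.
#'
#' @param field numeric array (1-3 dimensions, or a stack with subjects in
#'   the last dimension when `ndim` is given).
#' @param fwhm kernel full width at half maximum, in voxels.
#' @param ndim number of spatial axes to smooth over (defaults to all axes
#'   of `field`); axes beyond `ndim` are treated as independent replicates.
#' @returns array of the same shape.
#' @export
smooth_gaussian <- function(field, fwhm, ndim = NULL) {
  dims <- dim(field)
  if (is.null(dims)) dims <- length(field)
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(field)
  if (is.null(ndim)) ndim <- length(dims)
  kern <- gaussian_kernel_1d(fwhm)
  arr <- if (is.null(dim(field))) array(field, dims) else field
  conv_separable(arr, ndim, kern)
}

# Pointwise sd of unit-variance white noise after smooth_gaussian(), exact
# under zero padding: variance separates into a product over axes of
# rowSums(K_a^2).
smoothed_noise_sd_map <- function(dim, fwhm) {
  if (fwhm == 0) return(array(1, dim))
  kern <- gaussian_kernel_1d(fwhm)
  vecs <- lapply(dim, function(n) rowSums(conv_matrix_1d(n, kern)^2))
  v <- Reduce(function(acc, x) outer(acc, x), vecs)
  array(sqrt(v), dim)
}
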
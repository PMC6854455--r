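#' Specify a synthetic raw-effect signal
#'
#' Describes the phantoms used by the simulation framework: a linear ramp, a
#' smoothed disc ("circle", 2D), a smoothed ball ("sphere", 3D), a union of
#' four balls ("multi_sphere"), or a user-supplied mean image ("custom").
#'
#' @param kind one of `"ramp"`, `"circle"`, `"sphere"`, `"multi_sphere"`,
#'   `"custom"`.
#' @param shape lattice dimensions (length 2 or 3).
#' @param magnitude plateau height of the phantom before smoothing.
#' @param radius disc/ball radius in voxels (`circle`/`sphere`).
#' @param radii four radii for `multi_sphere`.
#' @param centers optional matrix of phantom centres (rows), in voxel
#'   coordinates; defaults to the lattice centre (single phantom) or four
#'   well-separated quadrant/octant centres (`multi_sphere`).
#' @param ramp_range `c(low, high)` endpoints of the ramp along the first
#'   axis.
#' @param fwhm Gaussian smoothing applied to the phantom, voxels.
#' @param rescale_to_max if non-`NULL`, the smoothed image is rescaled so
#'   its maximum equals this value (used for the 3D phantoms, whose peak is
#'   attenuated by smoothing).
#' @param values numeric array for `kind = "custom"` (used as-is; `fwhm` and
#'   `rescale_to_max` still apply).
#' @returns object of class `cs_signal_spec`.
#' @export
signal_spec <- function(kind = c("ramp", "circle", "sphere", "multi_sphere",
                                 "custom"),
                        shape, magnitude = 3, radius = NULL, radii = NULL,
                        centers = NULL, ramp_range = c(1, 3), fwhm = 3,
                        rescale_to_max = NULL, values = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% 2:3, all(shape >= 2L), fwhm >= 0)
  if (kind == "circle") stopifnot(length(shape) == 2L)
  if (kind %in% c("sphere", "multi_sphere")) stopifnot(length(shape) == 3L)
  if (kind %in% c("circle", "sphere")) {
    if (is.null(radius)) stop("radius required for kind = ", kind)
    stopifnot(radius > 0, all(2 * radius <= shape))
  }
  if (kind == "multi_sphere") {
    if (is.null(radii)) radii <- pmax(2, round(shape[1] * c(4, 8, 12, 16) / 100))
    stopifnot(length(radii) == 4L, all(radii > 0), all(2 * max(radii) <= shape))
  }
  if (kind == "custom") {
    stopifnot(!is.null(values),
              identical(as.integer(dim(values)), shape))
  }
  structure(list(kind = kind, shape = shape, magnitude = magnitude,
                 radius = radius, radii = radii, centers = centers,
                 ramp_range = ramp_range, fwhm = fwhm,
                 rescale_to_max = rescale_to_max, values = values),
            class = "cs_signal_spec")
}

# squared distance array from a centre point
dist2_from <- function(shape, centre) {
  grids <- lapply(seq_along(shape), function(a) {
    g <- (seq_len(shape[a]) - centre[a])^2
    dm <- rep(1L, length(shape)); dm[a] <- shape[a]
    array(rep(g, each = prod(shape[seq_len(a - 1L)])), shape)
  })
  Reduce(`+`, grids)
}

#' Realise a synthetic signal as a lattice image
#'
#' @param spec a [signal_spec()].
#' @returns numeric array of shape `spec$shape`.
#' @examples
#' mu <- make_signal(signal_spec("circle", shape = c(50, 50), magnitude = 3,
#'                               radius = 15, fwhm = 3))
#' range(mu)
#' @export
make_signal <- function(spec) {
  stopifnot(inherits(spec, "cs_signal_spec"))
  shape <- spec$shape
  img <- switch(
    spec$kind,
    ramp = {
      x <- seq(spec$ramp_range[1], spec$ramp_range[2], length.out = shape[1])
      array(rep(x, times = prod(shape[-1])), shape)
    },
    circle = ,
    sphere = {
      ctr <- if (is.null(spec$centers)) (shape + 1) / 2 else spec$centers[1, ]
      spec$magnitude * (dist2_from(shape, ctr) <= spec$radius^2)
    },
    multi_sphere = {
      ctrs <- spec$centers
      if (is.null(ctrs)) {
        fr <- rbind(c(.25, .25, .25), c(.75, .25, .50),
                    c(.25, .75, .50), c(.75, .75, .75))
        ctrs <- sweep(fr, 2L, shape, "*")
      }
      ind <- array(FALSE, shape)
      for (i in seq_len(4L)) {
        ind <- ind | (dist2_from(shape, ctrs[i, ]) <= spec$radii[i]^2)
      }
      spec$magnitude * ind
    },
    custom = spec$values
  )
  img <- smooth_gaussian(img + 0, spec$fwhm)
  if (!is.null(spec$rescale_to_max)) {
    mx <- max(img)
    if (mx <= 0) stop("cannot rescale a nonpositive signal")
    img <- img * (spec$rescale_to_max / mx)
  }
  img
}

#' Specify the subject-level noise field
#'
#' Subject noise is unit-variance Gaussian white noise, smoothed with a
#' Gaussian kernel, renormalised so its pointwise marginal sd is exactly 1
#' everywhere (smoothing shrinks the variance, and unevenly near the
#' border), then scaled by a target sd field: spatially constant, a linear
#' ramp along the last axis (y in 2D, z in 3D), or a user-supplied sd image.
#'
#' @param sd_structure `"constant"`, `"ramp"` or `"custom"`.
#' @param sd_value sd for `"constant"`.
#' @param sd_range `c(low, high)` for `"ramp"`.
#' @param fwhm smoothing kernel FWHM in voxels.
#' @param sd_field numeric array for `"custom"` (must be positive).
#' @returns object of class `cs_noise_spec`.
#' @export
noise_spec <- function(sd_structure = c("constant", "ramp", "custom"),
                       sd_value = 1, sd_range = c(0.5, 1.5), fwhm = 3,
                       sd_field = NULL) {
  sd_structure <- match.arg(sd_structure)
  stopifnot(fwhm >= 0)
  if (sd_structure == "constant") stopifnot(sd_value > 0)
  if (sd_structure == "ramp") stopifnot(all(sd_range > 0))
  if (sd_structure == "custom") stopifnot(!is.null(sd_field), all(sd_field > 0))
  structure(list(sd_structure = sd_structure, sd_value = sd_value,
                 sd_range = sd_range, fwhm = fwhm, sd_field = sd_field),
            class = "cs_noise_spec")
}

#' Target sd field implied by a noise specification
#' @param spec a [noise_spec()].
#' @param shape lattice dimensions.
#' @returns numeric array of shape `shape`.
#' @export
make_sd_field <- function(spec, shape) {
  stopifnot(inherits(spec, "cs_noise_spec"))
  shape <- as.integer(shape)
  switch(
    spec$sd_structure,
    constant = array(spec$sd_value, shape),
    ramp = {
      a <- length(shape)
      g <- seq(spec$sd_range[1], spec$sd_range[2], length.out = shape[a])
      array(rep(g, each = prod(shape[-a])), shape)
    },
    custom = {
      stopifnot(identical(as.integer(dim(spec$sd_field)), shape))
      spec$sd_field
    }
  )
}

#' Draw a stack of subject noise fields
#'
#' Each subject field is independent smoothed Gaussian noise with pointwise
#' marginal sd exactly equal to the target sd field of `spec` (see
#' [noise_spec()] for the renormalisation convention). Draws come from the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param spec a [noise_spec()].
#' @param n number of subject fields.
#' @param shape lattice dimensions.
#' @returns array of shape `c(shape, n)`.
#' @export
make_noise <- function(spec, n, shape) {
  stopifnot(inherits(spec, "cs_noise_spec"), n >= 1)
  shape <- as.integer(shape)
  arr <- array(rnorm(prod(shape) * n), c(shape, n))
  sd_field <- make_sd_field(spec, shape)
  scale <- if (spec$fwhm > 0) {
    arr <- smooth_gaussian(arr, spec$fwhm, ndim = length(shape))
    sd_field / smoothed_noise_sd_map(shape, spec$fwhm)
  } else {
    sd_field
  }
  arr * as.vector(scale)                  # recycles over the subject axis
}
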
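#' Read a stack of subject contrast images
#'
#' Accepts either one 4D NIfTI volume (subjects along the fourth axis) or a
#' vector of 3D volume paths on identical grids. The analysis mask is the
#' supplied mask intersected with the voxels where every subject image is
#' finite; with no mask file, the finite-value conjunction alone.
#'
#' @param paths character vector of NIfTI paths (one 4D file, or several 3D
#'   files).
#' @param mask_path optional NIfTI mask path (nonzero = in-mask).
#' @returns list with `data` (array `c(dim, N)`), `mask` (logical array),
#'   `dim`, `n`, and `template` (the first input's `niftiImage`, carrying
#'   the affine/header for writing results on the same grid).
#' @export
read_image_stack <- function(paths, mask_path = NULL) {
  stopifnot(length(paths) >= 1L)
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  if (length(paths) == 1L) {
    d <- dims[[1L]]
    if (!(length(d) %in% 3:4)) {
      stop("single input must be a 3D or 4D volume; got ", length(d), "D")
    }
    if (length(d) == 3L) d <- c(d, 1L)   # one-subject stack
    data <- array(as.numeric(imgs[[1L]]), d)
    ldim <- d[1:3]
  } else {
    ldim <- dims[[1L]]
    if (length(ldim) != 3L) stop("multiple inputs must each be 3D volumes")
    for (i in seq_along(dims)) {
      if (!identical(as.integer(dims[[i]]), as.integer(ldim))) {
        stop("grid mismatch: ", paths[i], " has dimensions ",
             paste(dims[[i]], collapse = "x"), ", expected ",
             paste(ldim, collapse = "x"))
      }
    }
    data <- array(unlist(imgs, use.names = FALSE), c(ldim, length(imgs)))
  }
  n <- dim(data)[4L]
  finite <- array(rowSums(!is.finite(matrix(data, ncol = n))) == 0L, ldim)
  mask <- finite
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    if (!identical(as.integer(dim(m)), as.integer(ldim))) {
      stop("mask grid ", paste(dim(m), collapse = "x"),
           " does not match data grid ", paste(ldim, collapse = "x"))
    }
    mask <- mask & (as.numeric(m) != 0)
  }
  if (!any(mask)) stop("empty analysis mask")
  list(data = data, mask = mask, dim = as.integer(ldim), n = n,
       template = imgs[[1L]])
}

#' Read a design matrix and contrast from headered CSVs
#'
#' @param design_path CSV with one row per subject and one column per design
#'   regressor (header row required).
#' @param contrast either a numeric vector, a comma-separated string
#'   (`"1,-1"`), or a path to a one-row headered CSV.
#' @returns a [design_spec()].
#' @export
read_design <- function(design_path, contrast) {
  X <- as.matrix(utils::read.csv(design_path, check.names = FALSE))
  w <- if (is.numeric(contrast)) {
    contrast
  } else if (file.exists(contrast)) {
    as.numeric(utils::read.csv(contrast, check.names = FALSE)[1L, ])
  } else {
    as.numeric(strsplit(contrast, ",", fixed = TRUE)[[1L]])
  }
  design_spec(X, w)
}

#' Write confidence sets as NIfTI masks plus a JSON sidecar
#'
#' Writes `<prefix>_upper.nii.gz`, `<prefix>_lower.nii.gz`,
#' `<prefix>_point_estimate.nii.gz` (uint8 binary masks),
#' `<prefix>_labels.nii.gz` (the nesting label map of [cs_label_map()]), and
#' `<prefix>.json` recording threshold, level, critical value and bootstrap
#' settings.
#'
#' @param cs a `cs_confidence_sets`.
#' @param prefix output path prefix.
#' @param template optional `niftiImage` whose header/affine the outputs
#'   inherit (e.g. from [read_image_stack()]).
#' @returns invisibly, the named vector of files written.
#' @export
write_confidence_sets <- function(cs, prefix, template = NULL) {
  stopifnot(inherits(cs, "cs_confidence_sets"))
  wr <- function(arr, path, dt) {
    img <- array(as.numeric(arr), cs$dim)
    if (!is.null(template)) {
      img <- RNifti::asNifti(img, reference = template)
    }
    RNifti::writeNifti(img, path, datatype = dt)
    path
  }
  files <- c(
    upper = wr(cs$upper, paste0(prefix, "_upper.nii.gz"), "uint8"),
    lower = wr(cs$lower, paste0(prefix, "_lower.nii.gz"), "uint8"),
    point_estimate = wr(cs$point_estimate,
                        paste0(prefix, "_point_estimate.nii.gz"), "uint8"),
    labels = wr(cs_label_map(cs), paste0(prefix, "_labels.nii.gz"), "uint8"),
    sidecar = paste0(prefix, ".json")
  )
  meta <- c(list(c = cs$c, alpha = cs$alpha, k = cs$k, vw = cs$vw),
            cs$settings[setdiff(names(cs$settings), c("c", "alpha", "k"))])
  jsonlite::write_json(meta, files[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}

#' Build a simulation configuration from a YAML file
#'
#' The YAML mirrors [simulation_config()]: top-level keys `signal`, `noise`,
#' `n`, `trials`, `c`, `alphas`, `B`, `methods`, `boundaries`, `seed`, where
#' `signal` and `noise` hold the arguments of [signal_spec()] and
#' [noise_spec()]. Alternatively a top-level `preset:` name (plus optional
#' `scale`, `n`, `noise_sd` and overrides) selects a [sim_preset()].
#'
#' @param path YAML file path.
#' @returns a `cs_sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as boolean FALSE; undo that
  names(y)[names(y) == "FALSE"] <- "n"
  if (!is.null(y$preset)) {
    args <- y[setdiff(names(y), "preset")]
    return(do.call(sim_preset, c(list(name = y$preset), args)))
  }
  stopifnot(!is.null(y$signal), !is.null(y$noise))
  y$signal$shape <- as.integer(unlist(y$signal$shape))
  sig <- do.call(signal_spec, y$signal)
  noi <- do.call(noise_spec, y$noise)
  rest <- y[setdiff(names(y), c("signal", "noise"))]
  if (!is.null(rest$methods)) {
    rest$methods <- lapply(rest$methods, function(m) {
      list(multiplier = m$multiplier, variant = m$variant)
    })
  }
  do.call(simulation_config, c(list(signal = sig, noise = noi), rest))
}
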
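#' @importFrom stats rnorm qnorm sd quantile
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# Internal helpers for D-dimensional scalar lattices (D in {2, 3}) and stacks
# of subject images. A "stack" is canonically an array with dimensions
# (d_1, ..., d_D, N); internally most computation uses the N x V matrix
# unfolding (V = prod(lattice dims), column-major voxel order).

#' Coerce a subject-image stack to its V x N matrix unfolding
#'
#' Canonical stack layout is an array `c(dim, N)` (lattice axes first,
#' subjects last); its memory order is already the V x N unfolding so no
#' copy beyond a `dim<-` is needed. An N x V matrix (one row per subject,
#' the natural design-matrix orientation) is accepted with an explicit
#' `dim` and transposed.
#'
#' A V x N matrix (voxels by subjects) with a known lattice `dim` is used
#' as-is, copy-free.
#'
#' @returns list with `vmat` (V x N), `dim`, `n`.
#' @keywords internal
as_stack_vmat <- function(data, dim = NULL) {
  if (is.matrix(data) && !is.null(dim)) {
    v <- prod(dim)
    if (nrow(data) == v && ncol(data) != v) {
      return(list(vmat = data, dim = as.integer(dim), n = ncol(data)))
    }
    if (ncol(data) == v) {
      return(list(vmat = t(data), dim = as.integer(dim), n = nrow(data)))
    }
    stop("matrix dimensions match neither the N x V nor the V x N unfolding")
  }
  d <- base::dim(data)
  if (is.null(d) || length(d) < 3L) {
    stop("`data` must be an array with lattice dimensions first and subjects last")
  }
  ldim <- d[-length(d)]
  n <- d[length(d)]
  vmat <- data
  base::dim(vmat) <- c(prod(ldim), n)
  list(vmat = vmat, dim = as.integer(ldim), n = as.integer(n))
}

#' Default mask: everything in-lattice
#' @keywords internal
full_mask <- function(dim) array(TRUE, dim = dim)

check_mask <- function(mask, dim) {
  if (is.null(mask)) return(full_mask(dim))
  if (!is.logical(mask)) mask <- array(as.logical(mask), dim = base::dim(mask))
  stopifnot(identical(as.integer(base::dim(mask)), as.integer(dim)))
  if (!any(mask)) stop("mask is empty")
  mask
}

#' Convert a linear voxel index to lattice coordinates
#' @keywords internal
index_to_coord <- function(idx, dim) {
  arrayInd(idx, .dim = dim)
}

# Row-wise maximum of the absolute value of a matrix, without apply().
row_max_abs <- function(x) {
  a <- abs(x)
  j <- max.col(a, ties.method = "first")
  a[cbind(seq_len(nrow(a)), j)]
}
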
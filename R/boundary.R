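#' Locate lattice edges straddling a level set, with interpolation weights
#'
#' Scans every axis-adjacent pair of masked voxels (4-neighbourhood in 2D,
#' 6-neighbourhood in 3D) and keeps the ordered pairs `(s_I, s_O)` with
#' `field(s_I) >= c` (inside the excursion set; ties count as inside) and
#' `field(s_O) < c`. Each edge carries the linear-interpolation weights
#' placing the level-c crossing between the two voxels:
#' `m1 = (f_I - c) / (f_I - f_O)` for the outside voxel and
#' `m2 = (c - f_O) / (f_I - f_O)` for the inside voxel, so that
#' `m1 * f_O + m2 * f_I = c` exactly.
#'
#' @param field numeric array (2D or 3D).
#' @param c level-set threshold, in the units of `field`.
#' @param mask optional logical array; pairs with either endpoint off-mask
#'   are skipped — the boundary is only estimated where both ends are
#'   observed.
#' @param source label recorded on the result (`"estimated"` for a fitted
#'   contrast map, `"true"` for a known mean).
#' @returns an object of class `cs_boundary`: a tibble with columns
#'   `inside`, `outside` (linear voxel indices), `axis`, `m1`, `m2`, plus
#'   attributes `dim`, `c`, `source`.
#' @details Errors if the excursion set `{field >= c}` is empty within the
#'   mask, or if it is non-empty but no in-mask crossing edge exists (e.g.
#'   the excursion set fills the whole mask): in either case there is no
#'   boundary on which to calibrate a critical value.
#' @examples
#' f <- array(c(1, 4), c(2, 1))
#' find_boundary_edges(f, 2)  # one edge, m1 = 2/3, m2 = 1/3
#' @export
find_boundary_edges <- function(field, c, mask = NULL,
                                source = c("estimated", "true")) {
  source <- match.arg(source)
  dims <- dim(field)
  if (is.null(dims) || !(length(dims) %in% 1:3)) {
    stop("`field` must be a 1D-3D array")
  }
  mask <- check_mask(mask, dims)
  if (any(!is.finite(field[mask]))) stop("field has non-finite values in mask")

  inside_set <- (field >= c) & mask
  if (!any(inside_set)) {
    stop("excursion set {field >= ", c, "} is empty within the mask; ",
         "cannot locate a boundary")
  }
  below <- (field < c) & mask

  ins <- integer(0); out <- integer(0); ax <- integer(0)
  nvox <- prod(dims)
  all_idx <- seq_len(nvox)
  for (a in seq_along(dims)) {
    if (dims[a] < 2L) next
    off <- prod(dims[seq_len(a - 1L)])
    has_next <- as.vector(slice.index(field, a) < dims[a])
    lo <- all_idx[has_next]
    hi <- lo + off
    # inside at lo, outside at hi
    e1 <- lo[inside_set[lo] & below[hi]]
    # inside at hi, outside at lo
    e2 <- lo[inside_set[hi] & below[lo]]
    ins <- c(ins, e1, e2 + off)
    out <- c(out, e1 + off, e2)
    ax <- c(ax, rep.int(a, length(e1) + length(e2)))
  }
  if (length(ins) == 0L) {
    stop("excursion set has no in-mask boundary edges at c = ", c,
         "; cannot calibrate a critical value")
  }
  f_i <- field[ins]
  f_o <- field[out]
  den <- f_i - f_o
  stopifnot(all(den > 0))
  edges <- tibble::tibble(
    inside = ins, outside = out, axis = ax,
    m1 = (f_i - c) / den, m2 = (c - f_o) / den
  )
  structure(edges, dim_lattice = dims, c = c, source = source,
            class = c("cs_boundary", class(edges)))
}

#' Interpolate a subject stack onto boundary crossing points
#'
#' Evaluates each subject image at the sub-voxel crossing points of a
#' [find_boundary_edges()] result by the same linear weights:
#' entry `(i, e)` is `m1 * stack_i(outside_e) + m2 * stack_i(inside_e)`.
#' Applied to standardized residuals this yields the residual field sampled
#' on the (estimated or true) excursion-set boundary, the input to the
#' multiplier bootstrap.
#'
#' @param stack subject images: `c(dim, N)` array, V x N matrix (the
#'   layout of `fit_glm()$std_residuals`) or N x V matrix.
#' @param edges a `cs_boundary`.
#' @returns numeric N x E matrix, E = number of edges.
#' @export
interpolate_to_boundary <- function(stack, edges) {
  stopifnot(inherits(edges, "cs_boundary"))
  dims <- attr(edges, "dim_lattice")
  s <- as_stack_vmat(stack, dim = dims)
  if (!identical(as.integer(s$dim), as.integer(dims))) {
    stop("stack lattice ", paste(s$dim, collapse = "x"),
         " does not match boundary lattice ", paste(dims, collapse = "x"))
  }
  a_out <- s$vmat[edges$outside, , drop = FALSE]   # E x N
  a_in <- s$vmat[edges$inside, , drop = FALSE]
  t(a_out * edges$m1 + a_in * edges$m2)
}
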
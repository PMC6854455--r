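#' Direct lattice check of the subset condition
#'
#' Declares a simulated trial covered when, voxel by voxel on the mask,
#' the upper confidence set lies inside the true excursion set and the true
#' excursion set lies inside the lower confidence set.
#'
#' @param true_set logical array: the lattice representation of the true
#'   excursion set `{mu >= c}`.
#' @param cs a `cs_confidence_sets` on the same lattice.
#' @returns TRUE/FALSE.
#' @export
assess_lattice <- function(true_set, cs) {
  stopifnot(inherits(cs, "cs_confidence_sets"),
            identical(as.integer(dim(true_set)), as.integer(cs$dim)))
  m <- cs$mask
  up_ok <- !any(cs$upper[m] & !true_set[m])
  lo_ok <- !any(true_set[m] & !cs$lower[m])
  up_ok && lo_ok
}

#' Interpolated check of the subset condition on the true boundary
#'
#' The lattice comparison misses sub-voxel upcrossings: the confidence-set
#' boundaries can slip across the true continuous boundary between lattice
#' points without any voxel membership changing, which inflates empirical
#' coverage. This check works at the sub-voxel crossing points `s*` of the
#' *true* boundary (known in simulation): for each edge of the true
#' excursion set at threshold `c`, with linear weights `m1, m2`, it declares
#'
#' * an upper violation when
#'   `m1 (g(s_O) - k sigma(s_O) v_w) + m2 (g(s_I) - k sigma(s_I) v_w) >= c`
#'   (the interpolated upper set reaches the true boundary point), and
#' * a lower violation when the analogous `+ k` combination falls below `c`
#'   (the interpolated lower set fails to contain it),
#'
#' where `g` is the fitted contrast. Covered means no violation at any `s*`.
#'
#' @param mu numeric array: the true, noise-free contrast field.
#' @param fit the [fit_glm()] result for the trial.
#' @param cs the `cs_confidence_sets` built from `fit` (supplies `k`, `c`).
#' @returns TRUE/FALSE.
#' @details Errors when the true excursion set has no boundary inside the
#'   mask: a simulated truth must cross the threshold inside the domain for
#'   coverage of its boundary to be assessable.
#' @export
assess_interpolated <- function(mu, fit, cs) {
  stopifnot(inherits(fit, "cs_glm"), inherits(cs, "cs_confidence_sets"),
            identical(as.integer(dim(mu)), as.integer(fit$dim)))
  edges <- tryCatch(
    find_boundary_edges(mu, cs$c, mask = fit$mask, source = "true"),
    error = function(e) {
      stop("cannot assess interpolated coverage: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  g <- fit$contrast
  half <- cs$k * fit$sigma * fit$vw
  upper_val <- edges$m1 * (g[edges$outside] - half[edges$outside]) +
    edges$m2 * (g[edges$inside] - half[edges$inside])
  lower_val <- edges$m1 * (g[edges$outside] + half[edges$outside]) +
    edges$m2 * (g[edges$inside] + half[edges$inside])
  !any(upper_val >= cs$c) && !any(lower_val < cs$c)
}

#' Combined coverage verdict for a simulated trial
#'
#' A trial counts as covered only when both the direct lattice comparison
#' and the interpolated true-boundary check pass; the conjunction is never
#' more lenient than either check alone.
#'
#' @inheritParams assess_interpolated
#' @returns TRUE/FALSE.
#' @export
assess_trial <- function(mu, fit, cs) {
  assess_lattice(mu >= cs$c, cs) && assess_interpolated(mu, fit, cs)
}
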
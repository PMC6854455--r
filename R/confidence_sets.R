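#' Assemble confidence sets from a fit, a threshold and a critical value
#'
#' Thresholds the fitted contrast map three ways:
#' the point estimate `{w'betahat >= c}`, the upper confidence set
#' `{w'betahat >= c + k sigmahat v_w}` and the lower confidence set
#' `{w'betahat >= c - k sigmahat v_w}`. For `k >= 0` the three sets are
#' nested (upper within point estimate within lower); all respect the mask.
#' Ties go inside: every comparison is `>=`, so the sets are the closed
#' excursion sets of the shifted thresholds.
#'
#' @param fit a [fit_glm()] result.
#' @param c excursion threshold, raw effect units.
#' @param k nonnegative critical value (see [critical_value()]).
#' @param alpha optional significance level, recorded for provenance.
#' @param settings optional list of bootstrap settings, recorded verbatim.
#' @returns object of class `cs_confidence_sets`: logical arrays
#'   `point_estimate`, `upper`, `lower` (FALSE off-mask), plus `k`, `c`,
#'   `alpha`, `vw`, `mask`, `dim`, `settings`.
#' @export
construct_cs <- function(fit, c, k, alpha = NA_real_, settings = list()) {
  stopifnot(inherits(fit, "cs_glm"), is.numeric(k), length(k) == 1L, k >= 0)
  mvec <- fit$mask
  half <- k * fit$sigma * fit$vw
  mk <- function(thr) {
    out <- array(FALSE, fit$dim)
    out[mvec] <- fit$contrast[mvec] >= thr[mvec]
    out
  }
  thr0 <- array(c, fit$dim)
  structure(
    list(point_estimate = mk(thr0), upper = mk(thr0 + half),
         lower = mk(thr0 - half), k = k, c = c, alpha = alpha,
         vw = fit$vw, mask = fit$mask, dim = fit$dim, settings = settings),
    class = "cs_confidence_sets"
  )
}

#' End-to-end confidence sets for an excursion set, from data
#'
#' The practical pipeline: fit the voxelwise GLM, take the plug-in estimated
#' boundary of `{w'betahat >= c}`, interpolate the standardized residuals
#' onto it, bootstrap the boundary supremum, read off the `(1 - alpha)`
#' critical value `k`, and threshold. With simultaneous confidence
#' `1 - alpha` (asymptotically), every voxel in the upper set has true
#' contrast above `c` and every voxel outside the lower set has true
#' contrast below `c`.
#'
#' @inheritParams fit_glm
#' @param c excursion threshold, raw effect units (e.g. 0.25 %BOLD).
#' @param alpha significance level in (0, 1); confidence is `1 - alpha`.
#' @param config a [boot_config()].
#' @returns a `cs_confidence_sets`; `$settings` records `(c, alpha, B,
#'   multiplier, variant, seed, k)` and the boundary size.
#' @details Fails with an explanatory error when the estimated excursion set
#'   has no boundary within the mask (threshold too high or too low for
#'   these data) — the critical value cannot be calibrated there.
#' @examples
#' mu <- make_signal(signal_spec("circle", shape = c(32, 32), magnitude = 3,
#'                               radius = 10, fwhm = 3))
#' set.seed(7)
#' y <- sapply(1:20, function(i) mu + rnorm(length(mu), sd = 0.5))
#' dim(y) <- c(32, 32, 20)
#' cs <- compute_confidence_sets(y, design_spec(matrix(1, 20, 1), 1),
#'                               c = 2, alpha = 0.1,
#'                               config = boot_config(B = 200, seed = 1))
#' sum(cs$upper); sum(cs$point_estimate); sum(cs$lower)
#' @export
compute_confidence_sets <- function(data, design, c, alpha,
                                    config = boot_config(),
                                    mask = NULL, dim = NULL) {
  fit <- fit_glm(data, design, mask = mask, dim = dim)
  edges <- tryCatch(
    find_boundary_edges(fit$contrast, c, mask = fit$mask, source = "estimated"),
    error = function(e) {
      stop("cannot calibrate confidence sets: ", conditionMessage(e),
           ". Consider a different threshold c.", call. = FALSE)
    }
  )
  eps_b <- interpolate_to_boundary(fit$std_residuals, edges)
  sups <- bootstrap_sup_distribution(eps_b, config)
  k <- critical_value(sups, alpha)
  construct_cs(fit, c, k, alpha = alpha,
               settings = list(c = c, alpha = alpha, B = config$B,
                               multiplier = config$multiplier,
                               variant = config$variant, seed = config$seed,
                               k = k, n_boundary = nrow(edges)))
}

#' @export
print.cs_confidence_sets <- function(x, ...) {
  cat("Spatial confidence sets for {contrast >= ", x$c, "}\n", sep = "")
  if (!is.na(x$alpha)) cat("  confidence:", 1 - x$alpha, "\n")
  cat("  k =", format(x$k, digits = 4), " v_w =", format(x$vw, digits = 4), "\n")
  cat("  voxels: upper", sum(x$upper), "| point estimate",
      sum(x$point_estimate), "| lower", sum(x$lower),
      "| mask", sum(x$mask), "\n")
  invisible(x)
}

#' Label map encoding the nesting of the three sets
#'
#' 0 = outside all sets, 1 = lower only, 2 = point estimate (and lower),
#' 3 = upper (and both others). Because the sets are nested the three masks
#' are recoverable as `upper = lab == 3`, `point = lab >= 2`,
#' `lower = lab >= 1`.
#'
#' @param cs a `cs_confidence_sets`.
#' @returns integer array of labels.
#' @export
cs_label_map <- function(cs) {
  stopifnot(inherits(cs, "cs_confidence_sets"))
  lab <- array(0L, cs$dim)
  lab[cs$lower] <- 1L
  lab[cs$point_estimate] <- 2L
  lab[cs$upper] <- 3L
  lab
}

#' Summarise confidence sets as a one-row tibble
#'
#' @param x a `cs_confidence_sets`.
#' @param ... unused.
#' @returns tibble with threshold, confidence level, critical value and the
#'   voxel counts of the three sets.
#' @importFrom generics glance
#' @export
glance.cs_confidence_sets <- function(x, ...) {
  tibble::tibble(
    c = x$c, alpha = x$alpha, k = x$k, vw = x$vw,
    n_upper = sum(x$upper), n_point = sum(x$point_estimate),
    n_lower = sum(x$lower), n_mask = sum(x$mask)
  )
}

#' @export
generics::glance
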
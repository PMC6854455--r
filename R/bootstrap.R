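#' Multiplier bootstrap settings
#'
#' @param B number of bootstrap replicates.
#' @param multiplier `"rademacher"` (each multiplier +1/-1 with probability
#'   1/2) or `"gaussian"` (standard normal multipliers).
#' @param variant `"t"` for the studentized wild bootstrap (each replicate
#'   field is normalised pointwise by the sample sd of the multiplied
#'   residuals) or `"plain"` for the unstudentized version.
#' @param seed optional integer; when given, the bootstrap seeds its own
#'   reproducible stream, otherwise it draws from the current RNG state.
#' @returns an object of class `cs_boot_config`.
#' @export
boot_config <- function(B = 5000, multiplier = c("rademacher", "gaussian"),
                        variant = c("t", "plain"), seed = NULL) {
  multiplier <- match.arg(multiplier)
  variant <- match.arg(variant)
  B <- as.integer(B)
  stopifnot(B >= 1L)
  structure(list(B = B, multiplier = multiplier, variant = variant,
                 seed = seed), class = "cs_boot_config")
}

#' Bootstrap the supremum of the error field on the boundary
#'
#' Approximates the distribution of `sup |G|` over the level-set boundary,
#' where `G` is the limiting mean-zero, unit-variance error field of the
#' GLM. Replicate `b` draws multipliers `r_1..r_N`, forms the wild bootstrap
#' field `G*(s) = N^{-1/2} sum_i r_i eps_i(s)` at each boundary point `s`
#' (columns of `boundary_residuals`), for the studentized variant divides by
#' `sigma*(s)`, the sample sd (divisor N - 1) of the multiplied residuals
#' `{r_i eps_i(s)}`, and records the maximum absolute value over the
#' boundary.
#'
#' @param boundary_residuals N x E matrix of standardized residuals
#'   interpolated to the E boundary points ([interpolate_to_boundary()]).
#' @param config a [boot_config()].
#' @param multipliers optional B x N matrix of multipliers, overriding the
#'   random draw (used for exhaustive enumeration and diagnostics).
#' @returns object of class `cs_sup_dist`: list with `sups` (length B,
#'   nonnegative), and the settings used.
#' @details Replicate `b` consumes the `b`-th consecutive block of `N`
#'   multiplier draws from the stream, so results are reproducible for fixed
#'   `(seed, B, N)` regardless of vectorisation. A boundary point whose
#'   studentizing sd is exactly zero in some replicate (possible only with
#'   degenerate residuals) contributes 0 to that replicate's supremum and
#'   triggers a warning; aborting the replicate would bias the quantile.
#' @export
bootstrap_sup_distribution <- function(boundary_residuals, config = boot_config(),
                                       multipliers = NULL) {
  eps <- as.matrix(boundary_residuals)
  n <- nrow(eps)
  e <- ncol(eps)
  stopifnot(n >= 2L, e >= 1L)
  B <- config$B
  if (is.null(multipliers)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    draws <- if (config$multiplier == "gaussian") {
      rnorm(B * n)
    } else {
      sample(c(-1, 1), B * n, replace = TRUE)
    }
    R <- matrix(draws, nrow = B, ncol = n, byrow = TRUE)
  } else {
    R <- as.matrix(multipliers)
    stopifnot(ncol(R) == n)
    B <- nrow(R)
  }

  S <- R %*% eps                        # B x E, sum_i r_i eps_i(s)
  if (config$variant == "plain") {
    G <- S / sqrt(n)
  } else {
    m <- S / n
    ssq <- if (is.null(multipliers) && config$multiplier == "rademacher") {
      # r_i^2 = 1, so sum (r_i eps_i)^2 = sum eps_i^2: constant across b
      matrix(colSums(eps^2), nrow = B, ncol = e, byrow = TRUE)
    } else {
      (R^2) %*% (eps^2)
    }
    v <- (ssq - n * m^2) / (n - 1)
    v[v < 0] <- 0                       # guard rounding
    sdm <- sqrt(v)
    zero_sd <- sdm == 0
    if (any(zero_sd)) {
      warning("sigma* = 0 at ", sum(zero_sd),
              " boundary point/replicate combinations; contributing 0")
      sdm[zero_sd] <- Inf
    }
    G <- sqrt(n) * m / sdm
  }
  structure(list(sups = row_max_abs(G), B = B, n = n, n_boundary = e,
                 multiplier = config$multiplier, variant = config$variant),
            class = "cs_sup_dist")
}

#' Critical value from a bootstrap supremum distribution
#'
#' Returns the conservative empirical `(1 - alpha)` quantile: the
#' `ceiling((1 - alpha) * B)`-th smallest of the B suprema, with no
#' interpolation between order statistics, so the result is reproducible
#' bit-exactly and never anti-conservative relative to the usual
#' interpolated quantile.
#'
#' @param sups a `cs_sup_dist` or a numeric vector of suprema.
#' @param alpha significance level in (0, 1).
#' @returns nonnegative scalar `k`.
#' @examples
#' critical_value(1:100, alpha = 0.05)  # 95
#' @export
critical_value <- function(sups, alpha) {
  if (inherits(sups, "cs_sup_dist")) sups <- sups$sups
  sups <- as.numeric(sups)
  if (length(sups) == 0L) stop("empty supremum distribution")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  sort(sups)[ceiling((1 - alpha) * length(sups))]
}

#' @export
print.cs_sup_dist <- function(x, ...) {
  cat("Bootstrap supremum distribution (", x$variant, " variant, ",
      x$multiplier, " multipliers)\n", sep = "")
  cat("  B =", x$B, " subjects =", x$n, " boundary points =", x$n_boundary, "\n")
  cat("  quantiles:", paste(format(quantile(x$sups, c(.5, .8, .9, .95)),
                                   digits = 3), collapse = " "), "\n")
  invisible(x)
}
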
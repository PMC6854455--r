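#' Design specification for the mass-univariate GLM
#'
#' Bundles the between-subject design matrix and the contrast vector whose
#' fitted value `w'beta` carries the raw effect units of the data (e.g.
#' percent BOLD change). Validity (full column rank, more subjects than
#' parameters, non-null contrast) is checked here once so downstream code can
#' rely on it.
#'
#' @param X numeric design matrix, one row per subject image (N x p).
#' @param w numeric contrast vector of length p.
#' @returns an object of class `cs_design` with elements `X`, `w`, `n`, `p`.
#' @examples
#' design_spec(matrix(1, 10, 1), 1)           # one-sample mean
#' design_spec(cbind(g1 = rep(1:0, each = 3),
#'                   g2 = rep(0:1, each = 3)), c(1, -1))
#' @export
design_spec <- function(X, w) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  w <- as.numeric(w)
  n <- nrow(X)
  p <- ncol(X)
  if (length(w) != p) stop("contrast length ", length(w), " != ncol(X) = ", p)
  if (all(w == 0)) stop("contrast vector is all zero")
  if (n <= p) stop("need more subjects (", n, ") than design columns (", p, ")")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  structure(list(X = X, w = w, n = n, p = p), class = "cs_design")
}

#' Fit the voxelwise general linear model
#'
#' Fits `Y(s) = X beta(s) + eps(s)` independently at every masked voxel by
#' ordinary least squares and returns the pieces the confidence-set
#' construction needs: the contrast map `w'betahat`, the pointwise residual
#' standard deviation `sigmahat` (divisor N - p), the standardized residual
#' stack `(Y - X betahat) / sigmahat`, and the normalised contrast standard
#' deviation `v_w = sqrt(w'(X'X)^-1 w)`.
#'
#' @param data subject images: an array with lattice dimensions first and
#'   subjects last (`c(dim, N)`), or an N x V matrix together with `dim`.
#' @param design a [design_spec()].
#' @param mask optional logical array of lattice shape; voxels outside the
#'   mask are excluded from every computation and carried as `NA` in outputs.
#' @param dim lattice dimensions when `data` is a matrix.
#' @returns an object of class `cs_glm`: `contrast` and `sigma` arrays,
#'   `std_residuals` (V x N matrix, voxels in column-major lattice order by
#'   subjects, `NA` off-mask; reshape with `dim<- c(fit$dim, n)` for a
#'   stack), `vw`, `dof`, `mask`, `dim`, `design`.
#' @details A masked voxel where the residual variance is exactly zero (all
#'   subjects identical up to the fitted model) raises an error naming the
#'   voxel: the bootstrap is undefined there and silently clamping would hide
#'   pathological input.
#' @examples
#' y <- array(rnorm(8 * 8 * 12), c(8, 8, 12))
#' fit <- fit_glm(y, design_spec(matrix(1, 12, 1), 1))
#' fit$vw  # 1/sqrt(12) for the one-sample mean
#' @export
fit_glm <- function(data, design, mask = NULL, dim = NULL) {
  stopifnot(inherits(design, "cs_design"))
  s <- as_stack_vmat(data, dim = dim)              # V x N unfolding
  if (s$n != design$n) {
    stop("stack has ", s$n, " subjects but design has ", design$n, " rows")
  }
  mask <- check_mask(mask, s$dim)
  mvec <- as.vector(mask)
  all_in <- all(mvec)
  Y <- if (all_in) s$vmat else s$vmat[mvec, , drop = FALSE]
  if (anyNA(Y) || any(!is.finite(Y))) stop("non-finite values inside the mask")

  X <- design$X
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- (Y %*% X) %*% xtx_inv                    # Vm x p
  res <- Y - tcrossprod(beta, X)
  dof <- design$n - design$p
  sig <- sqrt(rowSums(res^2) / dof)
  # degenerate variance: zero up to the roundoff of the least-squares solve
  degen <- sig <= 1e-10 * (sqrt(rowSums(Y^2) / design$n) + 1e-300)
  if (any(degen)) {
    bad <- which(mvec)[which(degen)[1L]]
    co <- index_to_coord(bad, s$dim)
    stop("degenerate variance (sigma = 0) at voxel (",
         paste(co, collapse = ", "), ")")
  }
  contrast_m <- drop(beta %*% design$w)
  std_res <- res / sig                             # recycles down columns
  vw <- sqrt(drop(t(design$w) %*% xtx_inv %*% design$w))

  if (all_in) {
    contrast <- array(contrast_m, s$dim)
    sigma <- array(sig, s$dim)
    stdres_full <- std_res
  } else {
    contrast <- array(NA_real_, s$dim)
    sigma <- array(NA_real_, s$dim)
    contrast[mvec] <- contrast_m
    sigma[mvec] <- sig
    stdres_full <- matrix(NA_real_, prod(s$dim), s$n)
    stdres_full[mvec, ] <- std_res
  }

  structure(
    list(contrast = contrast, sigma = sigma, std_residuals = stdres_full,
         vw = vw, dof = dof, mask = mask, dim = s$dim, design = design),
    class = "cs_glm"
  )
}

#' @export
print.cs_glm <- function(x, ...) {
  cat("Voxelwise GLM fit\n")
  cat("  lattice:", paste(x$dim, collapse = " x "),
      " masked voxels:", sum(x$mask), "\n")
  cat("  subjects:", x$design$n, " dof:", x$dof,
      " v_w:", format(x$vw, digits = 4), "\n")
  rng <- range(x$contrast[x$mask])
  cat("  contrast range: [", format(rng[1], digits = 4), ",",
      format(rng[2], digits = 4), "]\n")
  invisible(x)
}
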
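# Shared fixtures: everything is generated in code at test time.

# A small noisy one-sample stack around a given mean image.
make_stack <- function(mu, n, sd = 1, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(length(mu) * n, sd = sd), c(dim(mu), n))
  arr + as.vector(mu)
}

# Smooth random field on a small lattice (for property-style loops).
random_smooth_field <- function(shape, seed, fwhm = 2) {
  set.seed(seed)
  smooth_gaussian(array(rnorm(prod(shape)), shape), fwhm)
}

# Minimal fitted-model object for unit tests that exercise set construction
# and assessment without a full GLM fit.
make_fake_fit <- function(contrast, sigma = NULL, vw = 1, mask = NULL) {
  dm <- dim(contrast)
  if (is.null(sigma)) sigma <- array(1, dm)
  if (is.null(mask)) mask <- array(TRUE, dm)
  structure(
    list(contrast = contrast, sigma = sigma, std_residuals = NULL,
         vw = vw, dof = NA_integer_, mask = mask, dim = as.integer(dm),
         design = NULL),
    class = "cs_glm"
  )
}

# Brute-force boundary-edge oracle: scan every ordered axis-adjacent pair.
brute_edges <- function(field, c, mask = NULL) {
  dims <- dim(field)
  if (is.null(mask)) mask <- array(TRUE, dims)
  out <- list()
  idx <- which(array(TRUE, dims))
  co <- arrayInd(idx, dims)
  for (i in idx) {
    for (a in seq_along(dims)) {
      step <- prod(dims[seq_len(a - 1)])
      ci <- arrayInd(i, dims)
      if (ci[a] < dims[a]) {
        j <- i + step
        for (pair in list(c(i, j), c(j, i))) {
          p <- pair[1]; q <- pair[2]
          if (mask[p] && mask[q] && field[p] >= c && field[q] < c) {
            den <- field[p] - field[q]
            out[[length(out) + 1]] <- data.frame(
              inside = p, outside = q,
              m1 = (field[p] - c) / den, m2 = (c - field[q]) / den)
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

# Canonical ordering for comparing edge sets.
edge_key <- function(df) {
  o <- order(df$inside, df$outside)
  df <- df[o, c("inside", "outside", "m1", "m2")]
  rownames(df) <- NULL
  df
}

# All 2^n Rademacher sign vectors as rows.
all_sign_matrices <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  colnames(g) <- NULL
  g
}
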
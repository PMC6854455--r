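test_that("the ramp spans its range along x and is constant along y", {
  mu <- make_signal(signal_spec("ramp", c(100, 100), ramp_range = c(1, 3),
                                fwhm = 0))
  expect_equal(mu[1, ], rep(1, 100))
  expect_equal(mu[100, ], rep(3, 100))
  expect_equal(mu[37, ], rep(mu[37, 1], 100))
  expect_equal(mu[, 50], seq(1, 3, length.out = 100))
})

test_that("an unsmoothed circle is the exact scaled disc indicator", {
  mu <- make_signal(signal_spec("circle", c(100, 100), magnitude = 3,
                                radius = 30, fwhm = 0))
  ctr <- (c(100, 100) + 1) / 2
  d2 <- outer((1:100 - ctr[1])^2, (1:100 - ctr[2])^2, `+`)
  expect_identical(mu, 3 * (d2 <= 900) + 0)
})

test_that("rescaled smoothed phantoms peak at exactly the target", {
  mu <- make_signal(signal_spec("sphere", c(30, 30, 30), magnitude = 3,
                                radius = 8, fwhm = 3, rescale_to_max = 3))
  expect_equal(max(mu), 3)
  mu4 <- make_signal(signal_spec("multi_sphere", c(40, 40, 40), magnitude = 3,
                                 radii = c(3, 4, 5, 6), fwhm = 3,
                                 rescale_to_max = 3))
  expect_equal(max(mu4), 3)
  # each default octant centre carries a strong blob
  ctrs <- round(rbind(c(.25, .25, .25), c(.75, .25, .5),
                      c(.25, .75, .5), c(.75, .75, .75)) * 40)
  expect_true(all(mu4[ctrs] > 2))
})

test_that("signal specifications are validated", {
  expect_error(signal_spec("circle", c(20, 20), radius = 15), "radius")
  expect_error(signal_spec("sphere", c(20, 20), radius = 5), "== 3")
  expect_error(signal_spec("nope", c(20, 20)), "arg")
  expect_error(signal_spec("custom", c(4, 4)), "values")
})

test_that("Gaussian smoothing is the identity at zero width and mass-preserving inside", {
  f <- random_smooth_field(c(12, 12), seed = 3, fwhm = 0)
  expect_identical(smooth_gaussian(f, 0), f)

  cst <- array(2, c(21, 21))
  sm <- smooth_gaussian(cst, 3)
  # interior unchanged (kernel sums to one); border attenuated by zero padding
  expect_equal(sm[8:14, 8:14], cst[8:14, 8:14], tolerance = 1e-12)
  expect_lt(sm[1, 11], 2)

  # an impulse reproduces the separable kernel values directly
  imp <- array(0, c(21, 21)); imp[11, 11] <- 1
  smi <- smooth_gaussian(imp, 3)
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); w <- w / sum(w)
  expect_equal(smi[11, 11 + (-r:r)], w * w[r + 1], tolerance = 1e-12)
  expect_equal(smi[11 + (-r:r), 11], w * w[r + 1], tolerance = 1e-12)
  expect_equal(smi[11 + 1, 11 + 1], w[r + 2]^2, tolerance = 1e-12)
})

test_that("smoothed renormalised noise has unit pointwise sd everywhere", {
  set.seed(61)
  draws <- make_noise(noise_spec("constant", sd_value = 1, fwhm = 3),
                      n = 4000, shape = c(8, 8))
  sds <- apply(matrix(draws, 64, 4000), 1, sd)
  expect_lt(max(abs(sds - 1)), 0.06)       # MC tolerance at 4000 draws
  # border voxels included: renormalisation handles truncation exactly
  expect_lt(abs(sds[1] - 1), 0.06)
})

test_that("the sd ramp scales noise along the last axis", {
  spec <- noise_spec("ramp", sd_range = c(0.5, 1.5), fwhm = 0)
  sd_field <- make_sd_field(spec, c(6, 11))
  expect_equal(sd_field[, 1], rep(0.5, 6))
  expect_equal(sd_field[, 11], rep(1.5, 6))
  expect_equal(sd_field[3, ], seq(0.5, 1.5, length.out = 11))

  set.seed(62)
  draws <- make_noise(spec, n = 3000, shape = c(6, 11))
  m <- matrix(draws, 66, 3000)
  sds <- array(apply(m, 1, sd), c(6, 11))
  expect_equal(mean(sds[, 1]), 0.5, tolerance = 0.03)
  expect_equal(mean(sds[, 11]), 1.5, tolerance = 0.06)

  # 3D: ramp along z
  sd3 <- make_sd_field(spec, c(4, 4, 9))
  expect_equal(sd3[2, 3, ], seq(0.5, 1.5, length.out = 9))
})

test_that("smoothing induces the Gaussian-kernel spatial autocorrelation", {
  # white noise smoothed with a Gaussian of sd sigma has autocorrelation
  # exp(-lag^2 / (4 sigma^2))
  set.seed(63)
  draws <- make_noise(noise_spec("constant", fwhm = 3), n = 3000,
                      shape = c(24, 24))
  m <- matrix(draws, 24 * 24, 3000)
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  v1 <- m[12 + 24 * 11, ]                 # voxel (12, 12)
  for (lag in 1:2) {
    v2 <- m[12 + lag + 24 * 11, ]         # voxel (12 + lag, 12)
    expect_equal(cor(v1, v2), exp(-lag^2 / (4 * sigma^2)), tolerance = 0.025)
  }
})

test_that("unsmoothed unit noise is i.i.d. standard normal", {
  set.seed(64)
  draws <- make_noise(noise_spec("constant", fwhm = 0), n = 200,
                      shape = c(10, 10))
  ks <- suppressWarnings(stats::ks.test(as.vector(draws), "pnorm"))
  expect_gt(ks$p.value, 1e-3)
  expect_equal(sd(draws), 1, tolerance = 0.02)
  expect_equal(cor(draws[1, 1, ], draws[2, 1, ]), 0, tolerance = 0.2)
})
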
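test_that("all-ones multipliers annihilate one-sample residual fields", {
  # one-sample standardized residuals sum to zero over subjects, so the
  # unit-multiplier bootstrap field is identically zero
  mu <- array(2.5, c(4, 4))
  y <- make_stack(mu, n = 8, seed = 3)
  fit <- fit_glm(y, design_spec(matrix(1, 8, 1), 1))
  e <- find_boundary_edges(fit$contrast, median(fit$contrast))
  eb <- interpolate_to_boundary(fit$std_residuals, e)

  ones <- matrix(1, 10, 8)
  s <- bootstrap_sup_distribution(eb, boot_config(B = 10, variant = "plain"),
                                  multipliers = ones)
  expect_equal(s$sups, rep(0, 10), tolerance = 1e-12)
})

test_that("two-subject Rademacher sups follow the enumerable two-point law", {
  eps <- matrix(c(1, -1), 2, 1)        # N = 2, E = 1
  signs <- all_sign_matrices(2)
  s <- bootstrap_sup_distribution(
    eps, boot_config(multiplier = "rademacher", variant = "plain"),
    multipliers = signs)
  # (+,+) and (-,-) cancel; (+,-) and (-,+) give |1 -(-1)|/sqrt(2)
  expect_equal(sort(s$sups), c(0, 0, sqrt(2), sqrt(2)))

  set.seed(1)
  s2 <- bootstrap_sup_distribution(
    eps, boot_config(B = 4000, multiplier = "rademacher", variant = "plain"))
  expect_true(all(abs(s2$sups) < 1e-12 | abs(s2$sups - sqrt(2)) < 1e-12))
  expect_equal(mean(s2$sups < 1e-12), 0.5, tolerance = 0.05)
})

test_that("bootstrap fields are symmetric under global sign flips", {
  set.seed(21)
  eps <- matrix(rnorm(6 * 3), 6, 3)
  R <- matrix(sample(c(-1, 1), 20 * 6, TRUE), 20, 6)
  for (variant in c("plain", "t")) {
    cfg <- boot_config(multiplier = "rademacher", variant = variant)
    a <- bootstrap_sup_distribution(eps, cfg, multipliers = R)
    b <- bootstrap_sup_distribution(eps, cfg, multipliers = -R)
    expect_identical(a$sups, b$sups)
  }
})

test_that("exhaustive sign enumeration is invariant to flipping a residual row", {
  # the full 2^N Rademacher sup distribution must not change when one
  # subject's residual field changes sign
  set.seed(33)
  n <- 8
  eps <- matrix(rnorm(n * 3), n, 3)
  signs <- all_sign_matrices(n)
  for (variant in c("plain", "t")) {
    cfg <- boot_config(multiplier = "rademacher", variant = variant)
    base <- bootstrap_sup_distribution(eps, cfg, multipliers = signs)
    flipped <- eps; flipped[4, ] <- -flipped[4, ]
    alt <- bootstrap_sup_distribution(flipped, cfg, multipliers = signs)
    expect_equal(sort(base$sups), sort(alt$sups), tolerance = 1e-12)
  }
})

test_that("studentized sups match a literal per-replicate oracle", {
  set.seed(14)
  n <- 7; e <- 4; B <- 25
  eps <- matrix(rnorm(n * e), n, e)
  for (mult in c("rademacher", "gaussian")) {
    R <- if (mult == "rademacher") {
      matrix(sample(c(-1, 1), B * n, TRUE), B, n)
    } else {
      matrix(rnorm(B * n), B, n)
    }
    got <- bootstrap_sup_distribution(
      eps, boot_config(multiplier = mult, variant = "t"), multipliers = R)
    oracle <- vapply(seq_len(B), function(b) {
      re <- R[b, ] * eps                     # n x e
      g <- colSums(re) / sqrt(n) / apply(re, 2, sd)
      max(abs(g))
    }, numeric(1))
    expect_equal(got$sups, oracle, tolerance = 1e-12)
  }
})

test_that("plain Gaussian bootstrap matches its first two moments", {
  set.seed(8)
  n <- 12
  eps <- matrix(rnorm(n), n, 1)
  cfg <- boot_config(B = 40000, multiplier = "gaussian", variant = "plain",
                     seed = 99)
  s <- bootstrap_sup_distribution(eps, cfg)
  # with E = 1, sups = |G|: E[G^2] = mean of eps_i^2
  expect_equal(mean(s$sups^2), sum(eps^2) / n, tolerance = 0.03)
})

test_that("a zero studentizing sd contributes zero with a warning", {
  eps <- matrix(1, 2, 1)                  # r*eps always has sd 0 or mean 0
  signs <- all_sign_matrices(2)
  expect_warning(
    s <- bootstrap_sup_distribution(
      eps, boot_config(multiplier = "rademacher", variant = "t"),
      multipliers = signs),
    "sigma\\* = 0")
  expect_equal(s$sups, rep(0, 4))
})

test_that("the critical value is the conservative empirical quantile", {
  expect_equal(critical_value(1:100, alpha = 0.05), 95)
  expect_equal(critical_value(sample(1:100), alpha = 0.05), 95)
  expect_equal(critical_value(rep(3.3, 17), alpha = 0.5), 3.3)

  # sorting-count oracle: smallest s with #(sups <= s) >= ceil((1-a)B)
  set.seed(4)
  sups <- rexp(257)
  for (alpha in c(0.01, 0.05, 0.2, 0.5, 0.9)) {
    kk <- critical_value(sups, alpha)
    need <- ceiling((1 - alpha) * length(sups))
    expect_true(sum(sups <= kk) >= need)
    expect_true(all(sups[sups < kk] < kk))
    expect_equal(kk, min(sups[rank(sups, ties.method = "first") >= need]))
  }

  # nonincreasing in alpha
  ks <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5), critical_value, numeric(1),
               sups = sups)
  expect_true(all(diff(ks) <= 0))

  expect_error(critical_value(sups, 0), "alpha")
  expect_error(critical_value(sups, 1), "alpha")
  expect_error(critical_value(numeric(0), 0.1), "empty")
})

test_that("seeded bootstrap runs reproduce bit-identically", {
  set.seed(2)
  eps <- matrix(rnorm(10 * 3), 10, 3)
  cfg <- boot_config(B = 200, multiplier = "rademacher", variant = "t",
                     seed = 123)
  a <- bootstrap_sup_distribution(eps, cfg)
  b <- bootstrap_sup_distribution(eps, cfg)
  expect_identical(a$sups, b$sups)
})
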
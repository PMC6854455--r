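#' Configure a Monte-Carlo coverage experiment
#'
#' Bundles everything one signal-plus-noise coverage experiment needs. Each
#' trial simulates `n` subject images `Y_i = mu + eps_i` (the one-sample
#' instance of the GLM: design a column of ones, contrast 1), fits the
#' voxelwise model, calibrates the critical value by multiplier bootstrap on
#' the requested boundary (estimated from the fitted contrast, and/or the
#' true boundary of `mu`, which is only available in simulation), builds
#' the confidence sets at each `alpha`, and records whether the subset
#' condition held under the lattice, interpolated and combined assessments.
#'
#' Several bootstrap method settings — and several signals on the same
#' lattice — can be evaluated on the *same* simulated trials (common random
#' numbers), which is how method comparisons are made without confounding
#' by simulation noise.
#'
#' @param signal a [signal_spec()], or a named list of them sharing one
#'   lattice shape (each trial's noise fields are reused for every signal).
#' @param noise a [noise_spec()].
#' @param n subjects per trial; a vector requests several sample sizes,
#'   evaluated on nested subsets of the same simulated subjects (common
#'   random numbers), one coverage row set per size.
#' @param trials number of Monte-Carlo trials.
#' @param c excursion threshold.
#' @param alphas significance levels (vector allowed).
#' @param B bootstrap replicates per trial.
#' @param methods list of `list(multiplier =, variant =)` pairs.
#' @param boundaries subset of `c("estimated", "true")`.
#' @param seed master seed; every trial draws from an independent,
#'   reproducible substream derived from it.
#' @returns object of class `cs_sim_config`.
#' @export
simulation_config <- function(signal, noise, n, trials, c = 2, alphas = 0.05,
                              B = 1000,
                              methods = list(list(multiplier = "rademacher",
                                                  variant = "t")),
                              boundaries = "estimated", seed = 1) {
  n <- sort(unique(as.integer(n)))
  if (inherits(signal, "cs_signal_spec")) {
    signal <- list(signal = signal)
  }
  stopifnot(length(signal) >= 1,
            all(vapply(signal, inherits, TRUE, "cs_signal_spec")),
            inherits(noise, "cs_noise_spec"),
            length(n) >= 1, all(n >= 2), trials >= 1, B >= 1,
            all(alphas > 0 & alphas < 1),
            all(boundaries %in% c("estimated", "true")),
            length(methods) >= 1)
  if (is.null(names(signal))) {
    names(signal) <- paste0("signal", seq_along(signal))
  }
  shapes <- unique(lapply(signal, `[[`, "shape"))
  if (length(shapes) != 1L) stop("all signals must share one lattice shape")
  for (m in methods) {
    stopifnot(m$multiplier %in% c("gaussian", "rademacher"),
              m$variant %in% c("plain", "t"))
  }
  structure(list(signal = signal, noise = noise, n = n,
                 trials = as.integer(trials), c = c, alphas = alphas,
                 B = as.integer(B), methods = methods,
                 boundaries = boundaries, seed = as.integer(seed)),
            class = "cs_sim_config")
}

#' Named reduced- and full-scale simulation presets
#'
#' `scale = "desk"` presets reproduce each design at a resolution and trial
#' count suited to a single CPU (50 x 50 grids with radius-15 phantoms in
#' 2D; 40^3 grids with radius 4 / 12 phantoms in 3D; hundreds of trials;
#' B in the hundreds-to-thousand range). `scale = "full"` mirrors the
#' headline experimental designs (100 x 100 and 100^3 grids, radius 5 / 30
#' phantoms, 3000 trials, B = 5000).
#'
#' @param name one of `"ramp2d"`, `"circle2d"`, `"sphere_small3d"`,
#'   `"sphere_large3d"`, `"multi_sphere3d"`.
#' @param scale `"desk"` or `"full"`.
#' @param n subjects per trial.
#' @param noise_sd `"constant"` or `"ramp"` noise sd structure.
#' @param ... overrides passed to [simulation_config()] (e.g. `trials`,
#'   `B`, `methods`, `alphas`, `seed`, `boundaries`).
#' @returns a `cs_sim_config`.
#' @export
sim_preset <- function(name = c("circle2d", "ramp2d", "sphere_small3d",
                                "sphere_large3d", "multi_sphere3d"),
                       scale = c("desk", "full"), n = 60,
                       noise_sd = c("constant", "ramp"), ...) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  noise_sd <- match.arg(noise_sd)
  desk <- scale == "desk"
  shape2 <- if (desk) c(50L, 50L) else c(100L, 100L)
  shape3 <- if (desk) c(40L, 40L, 40L) else c(100L, 100L, 100L)
  signal <- switch(
    name,
    ramp2d = signal_spec("ramp", shape2, ramp_range = c(1, 3), fwhm = 0),
    circle2d = signal_spec("circle", shape2, magnitude = 3,
                           radius = if (desk) 15 else 30, fwhm = 3),
    sphere_small3d = signal_spec("sphere", shape3, magnitude = 3,
                                 radius = if (desk) 4 else 5, fwhm = 3,
                                 rescale_to_max = 3),
    sphere_large3d = signal_spec("sphere", shape3, magnitude = 3,
                                 radius = if (desk) 12 else 30, fwhm = 3,
                                 rescale_to_max = 3),
    multi_sphere3d = signal_spec("multi_sphere", shape3, magnitude = 3,
                                 fwhm = 3, rescale_to_max = 3)
  )
  noise <- noise_spec(noise_sd, sd_value = 1, sd_range = c(0.5, 1.5), fwhm = 3)
  is3d <- length(signal$shape) == 3L
  defaults <- list(signal = signal, noise = noise, n = n,
                   trials = if (!desk) 3000L else if (is3d) 300L else 500L,
                   c = 2, alphas = 0.05,
                   B = if (!desk) 5000L else if (is3d) 500L else 1000L)
  defaults$signal <- stats::setNames(list(signal), name)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# interpolated assessment reusing precomputed true-boundary edges
assess_interp_edges <- function(true_edges, contrast, sigma, vw, k, c) {
  half <- k * vw * sigma
  lo <- true_edges$m1 * (contrast[true_edges$outside] - half[true_edges$outside]) +
    true_edges$m2 * (contrast[true_edges$inside] - half[true_edges$inside])
  hi <- true_edges$m1 * (contrast[true_edges$outside] + half[true_edges$outside]) +
    true_edges$m2 * (contrast[true_edges$inside] + half[true_edges$inside])
  !any(lo >= c) && !any(hi < c)
}

#' Run a Monte-Carlo coverage experiment
#'
#' Executes the experiment described by a [simulation_config()] and returns
#' the empirical coverage table: one row per combination of signal, sample
#' size, significance level, bootstrap method, boundary choice and
#' assessment method (`"lattice"`, `"interpolated"`, and their conjunction
#' `"both"`), with a binomial 95% Monte-Carlo half-width. Fully reproducible from
#' `config$seed`; trials that degenerate (e.g. an empty estimated boundary)
#' are excluded and counted in `trials_failed`, never silently dropped.
#'
#' @param config a `cs_sim_config`.
#' @param progress print a dot every 50 trials.
#' @returns a tibble of class `cs_coverage_table`.
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "cs_sim_config"))
  sig_names <- names(config$signal)
  shape <- config$signal[[1L]]$shape
  mus <- lapply(config$signal, make_signal)
  true_edges <- lapply(mus, find_boundary_edges, c = config$c, source = "true")
  true_sets <- lapply(mus, function(mu) mu >= config$c)
  ns <- config$n
  n_max <- max(ns)
  v <- prod(shape)
  designs <- lapply(ns, function(n) design_spec(matrix(1, n, 1L), 1))

  set.seed(config$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, config$trials)

  key <- function(si, n, boundary, mi, alpha, assess) {
    paste(si, n, boundary, mi, alpha, assess, sep = "\r")
  }
  tally <- new.env(parent = emptyenv())
  add <- function(k_, ok) {
    cur <- if (is.null(tally[[k_]])) c(0L, 0L) else tally[[k_]]
    tally[[k_]] <- cur + c(as.integer(ok), 1L)
  }
  failed <- matrix(0L, length(sig_names), length(ns),
                   dimnames = list(sig_names, as.character(ns)))

  for (t in seq_len(config$trials)) {
    set.seed(trial_seeds[t])
    noise <- make_noise(config$noise, n_max, shape)
    dim(noise) <- c(v, n_max)

    for (si in seq_along(mus)) {
      y <- noise + as.vector(mus[[si]])
      for (ni in seq_along(ns)) {
        n <- ns[ni]
        yn <- if (n == n_max) y else y[, seq_len(n), drop = FALSE]
        fit <- fit_glm(yn, designs[[ni]], dim = shape)

        est_edges <- NULL
        if ("estimated" %in% config$boundaries) {
          est_edges <- tryCatch(
            find_boundary_edges(fit$contrast, config$c, mask = fit$mask),
            error = function(e) NULL
          )
          if (is.null(est_edges)) {
            failed[si, ni] <- failed[si, ni] + 1L
            next
          }
        }

        for (boundary in config$boundaries) {
          edges <- if (boundary == "estimated") est_edges else true_edges[[si]]
          eps_b <- interpolate_to_boundary(fit$std_residuals, edges)
          for (mi in seq_along(config$methods)) {
            m <- config$methods[[mi]]
            sups <- bootstrap_sup_distribution(
              eps_b, boot_config(B = config$B, multiplier = m$multiplier,
                                 variant = m$variant)
            )
            for (alpha in config$alphas) {
              k <- critical_value(sups, alpha)
              cs <- construct_cs(fit, config$c, k, alpha = alpha)
              lat <- assess_lattice(true_sets[[si]], cs)
              itp <- assess_interp_edges(true_edges[[si]], fit$contrast,
                                         fit$sigma, fit$vw, k, config$c)
              add(key(si, n, boundary, mi, alpha, "lattice"), lat)
              add(key(si, n, boundary, mi, alpha, "interpolated"), itp)
              add(key(si, n, boundary, mi, alpha, "both"), lat && itp)
            }
          }
        }
      }
    }
    if (progress && t %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")

  rows <- lapply(ls(tally), function(k_) {
    parts <- strsplit(k_, "\r", fixed = TRUE)[[1L]]
    si <- as.integer(parts[1L])
    mi <- as.integer(parts[4L])
    cnt <- tally[[k_]]
    p <- cnt[1L] / cnt[2L]
    tibble::tibble(
      signal = sig_names[si],
      n = as.integer(parts[2L]), alpha = as.numeric(parts[5L]),
      multiplier = config$methods[[mi]]$multiplier,
      variant = config$methods[[mi]]$variant,
      boundary = parts[3L], assessment = parts[6L],
      coverage = p,
      mc_halfwidth = 1.96 * sqrt(p * (1 - p) / cnt[2L]),
      trials = cnt[2L],
      trials_failed = failed[si, as.character(parts[2L])]
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$signal, out$n, out$boundary, out$multiplier,
                   out$variant, out$alpha, out$assessment), ]
  attr(out, "c") <- config$c
  attr(out, "B") <- config$B
  attr(out, "shape") <- shape
  class(out) <- c("cs_coverage_table", class(out))
  out
}
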
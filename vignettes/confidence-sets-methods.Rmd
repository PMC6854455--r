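---
title: "Spatial confidence sets for raw effect sizes: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial confidence sets for raw effect sizes: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copeSets)
```

## The inferential problem

Group-level task-fMRI analyses usually end in a thresholded statistic map:
voxels where a null hypothesis of *zero* effect is rejected. That says
nothing about *how large* the effect is. `copeSets` targets the complementary
question: where does the raw effect size — e.g. %BOLD change — exceed a
scientifically meaningful threshold $c$?

At every location $s$ of a compact domain $S \subset \mathbb{R}^D$
($D \in \{2,3\}$), the package assumes the mass-univariate general linear
model

$$Y(s) = X\beta(s) + \varepsilon(s),$$

with $Y(s)$ the $N$ subject-level contrast values at $s$, $X$ an $N \times p$
design matrix, and errors that are independent across subjects, mean zero,
with common pointwise variance $\sigma^2(s)$ and unspecified spatial
correlation. For a contrast vector $w$ chosen so that $w^\top\beta$ carries
raw effect units, the target of inference is the **excursion set**

$$A_c = \{s \in S : w^\top\beta(s) \ge c\}.$$

The method produces an **upper confidence set** $\hat{A}_c^+$ and a **lower
confidence set** $\hat{A}_c^-$,

$$\hat{A}_c^\pm = \{s : w^\top\hat\beta(s) \ge c \pm k\,\hat\sigma(s)\,v_w\},
\qquad v_w = \sqrt{w^\top (X^\top X)^{-1} w},$$

such that, simultaneously and asymptotically with probability $1-\alpha$,

$$\hat{A}_c^+ \subset A_c \subset \hat{A}_c^-.$$

Every voxel inside $\hat{A}_c^+$ can be declared to exceed $c$ in the
population; every voxel outside $\hat{A}_c^-$ to fall below $c$; and the band
$\hat{A}_c^- \setminus \hat{A}_c^+$ is a simultaneous confidence region for
the true excursion boundary $\partial A_c$. The limiting coverage equals
$P[\sup_{s \in \partial A_c} |G(s)| \le k]$ where $G$ is a mean-zero,
unit-variance Gaussian field with the spatial correlation of the errors —
so everything hinges on calibrating $k$ against the supremum of an unknown
field on an unknown boundary.

## Calibrating k: the wild multiplier bootstrap

The standardized residuals
$\tilde\varepsilon_i(s) = (Y_i(s) - (X\hat\beta)_i(s))/\hat\sigma(s)$
retain the spatial correlation of the errors. Multiplying them by i.i.d.
random signs or Gaussians $r_i^*$ and rescaling,

$$G^*(s) = \frac{1}{\sqrt{N}} \sum_{i=1}^N r_i^* \tilde\varepsilon_i(s),$$

regenerates a surrogate of $G$; repeating $B$ times and taking the
$(1-\alpha)$ quantile of $\sup_{\partial\hat{A}_c} |G^*|$ yields $k$. The
package implements the two axes along which this scheme varies:

* **multiplier**: `gaussian` ($r_i^* \sim N(0,1)$) or `rademacher`
  ($r_i^* = \pm 1$ with probability $1/2$);
* **variant**: `plain` (the field above) or the studentized `t` form

$$\tilde G^*(s) = \frac{1}{\sqrt{N}} \sum_{i=1}^N
  \frac{r_i^* \tilde\varepsilon_i(s)}{\hat\sigma^*(s)},$$

where $\hat\sigma^*(s)$ is the sample standard deviation (divisor $N-1$) of
the multiplied residuals $\{r_i^*\tilde\varepsilon_i(s)\}$ in the current
replicate. The studentized Rademacher combination — the *Wild t-Bootstrap* —
accounts for the estimation of $\sigma$ and is the default: the simulation
framework below shows the plain Gaussian bootstrap under-covers badly at
small $N$, while the studentized Rademacher form stays at or above nominal.

Numerical conventions, chosen once:

* $k$ is the $\lceil (1-\alpha) B \rceil$-th order statistic of the $B$
  suprema — no interpolation between order statistics, so the result is
  reproducible bit-exactly and errs on the conservative side by at most one
  order statistic.
* If $\hat\sigma^*(s) = 0$ at some boundary point in some replicate
  (possible only for degenerate residuals), that point contributes 0 to the
  replicate's supremum and a warning is raised; aborting the replicate would
  bias the quantile.
* Replicate $b$ consumes the $b$-th consecutive block of $N$ multiplier
  draws, so results are identical for fixed `(seed, B, N)` regardless of
  internal vectorisation. For Rademacher multipliers the studentizing sum of
  squares $\sum_i (r_i^*\tilde\varepsilon_i)^2 = \sum_i \tilde\varepsilon_i^2$
  is precomputed once per boundary — an exact algebraic identity, verified in
  the tests against a literal per-replicate oracle.

## The boundary on a lattice

Data live on a voxel lattice, but $\partial A_c$ is a continuous set. The
package locates every axis-adjacent pair of masked voxels $(s_I, s_O)$ with
$f(s_I) \ge c > f(s_O)$ and places the crossing by linear interpolation with
weights

$$m_1 = \frac{f(s_I) - c}{f(s_I) - f(s_O)}, \qquad
  m_2 = \frac{c - f(s_O)}{f(s_I) - f(s_O)},$$

for $s_O$ and $s_I$ respectively, so $m_1 f(s_O) + m_2 f(s_I) = c$ exactly.
The same weights interpolate the standardized residuals onto the crossing
points, where the bootstrap supremum is then taken. Conventions:

* adjacency is axis-aligned only (4-neighbourhood in 2D, 6 in 3D); diagonal
  pairs would over-sample corners;
* a voxel with $f(s) = c$ exactly belongs to the excursion set (all set
  definitions use $\ge$, closed sets);
* pairs with either endpoint outside the mask are skipped — the boundary is
  only estimated where both ends are observed;
* in practice $k$ is always calibrated on the plug-in boundary
  $\partial\hat{A}_c$ of the fitted contrast; the true boundary
  $\partial A_c$ is available as an option inside the simulation framework
  only, for method validation.

With the estimated $k$, `construct_cs()` thresholds the contrast map three
ways; nesting $\hat{A}_c^+ \subseteq \hat{A}_c \subseteq \hat{A}_c^-$ holds
by construction for $k \ge 0$.

## Assessing coverage honestly: the resolution problem

Validating the method by simulation requires deciding, per trial, whether
$\hat{A}_c^+ \subset A_c \subset \hat{A}_c^-$ held. Comparing the three sets
voxel-by-voxel (`assess_lattice()`) is positively biased: the confidence-set
boundary can slip across the true boundary *between* lattice points without
changing any voxel membership, so violations go unseen — increasingly so in
3D, where the lattice samples the boundary ever more sparsely relative to
its area.

`assess_interpolated()` therefore works at the sub-voxel crossing points
$s^*$ of the *true* boundary (known in simulation). Using the true-field
weights $m_1, m_2$ on each true-boundary edge, an upper violation is declared
when

$$m_1\big(g(s_O) - k\hat\sigma(s_O)v_w\big) +
  m_2\big(g(s_I) - k\hat\sigma(s_I)v_w\big) \ge c,$$

with $g = w^\top\hat\beta$ — the interpolated upper set has reached a point
of the true boundary — and a lower violation when the analogous $+k$
combination falls below $c$. A trial counts as covered (`assess_trial()`)
only when **both** the lattice and the interpolated checks pass; the
package treats the two checks as a conjunction since each catches violations
the other can miss, a combination rule the original description of the
procedure leaves implicit. The conjunction is never more
lenient than either check, and the coverage tables report all three columns
so the lattice-only inflation is visible directly.

## The synthetic-data generator

`make_signal()` reproduces the standard phantoms: a linear ramp rising from
1 to 3 along the x-axis; a circular phantom of magnitude 3 and radius 30
(2D, 100×100); spherical phantoms of radius 5 and 30 and a four-sphere
configuration (3D, 100³) — each smoothed with a 3-voxel-FWHM Gaussian
kernel, the 3D signals rescaled to a maximum of exactly 3. The 2D circle is
*not* rescaled (rescaling is a 3D-phantom convention). Subject noise
(`make_noise()`) is unit-variance Gaussian white noise smoothed with the
same 3-voxel-FWHM kernel and scaled by a target sd field: constant 1, or a
linear ramp 0.5→1.5 along the last axis.

Design choices a reader should know about:

* **Smoothing** is separable convolution with a truncated kernel
  ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, radius $\lceil 4\sigma\rceil$,
  normalised to sum 1) under zero padding.
* **Noise renormalisation.** Smoothing shrinks the marginal variance of
  white noise, unevenly near the borders. Because the sd fields are
  specified as the sd of the noise itself, the smoothed field is divided by
  its exact pointwise sd map (a closed form under zero padding) so the
  marginal sd equals the target everywhere, borders included. Whether the
  original experiments renormalised this way or applied the target sd to the
  pre-smoothing white noise is not documented; for the constant-sd designs
  the distinction is irrelevant to coverage (residual standardization
  removes any global scale), and pilot checks showed no sensitivity for the
  ramp design either.
* **Four-sphere radii** are not pinned by the published description;
  defaults are radii scaled as 4/8/12/16 voxels per 100 of grid length, at
  well-separated octant centres, and are configurable.
* **Sample-size sharing.** When a configuration lists several sample sizes,
  each trial simulates the largest and evaluates the smaller ones on nested
  subject subsets; several signals on one lattice likewise share each
  trial's noise fields. This is the usual common-random-numbers design for
  method comparison: per-cell coverage estimates are unchanged, comparisons
  across cells have less Monte-Carlo noise.
* **Reproducibility.** Trial $t$ reseeds from the $t$-th entry of a
  master-seeded seed table, so any trial can be replayed independently of
  the others.
* A trial whose estimated excursion set has no in-mask boundary cannot
  calibrate $k$; such trials are excluded and counted in `trials_failed`,
  never silently dropped.

## Simulation scales

The full published designs (100×100 and 100³ grids, 3000 trials, B = 5000)
are available as `sim_preset(..., scale = "full")`. The package's own test
and acceptance runs use reduced designs, chosen as the scales a single CPU
handles in minutes:

* 2D: the full 100×100 circle geometry (radius 30, FWHM 3) at 500–2500
  trials with B = 1000 — 2D trials are cheap, so only the trial count and B
  are reduced;
* 3D: a 40³ box with sphere radii 4 (small) and 12 (large), 300 trials,
  B = 500, N ∈ {60, 120}. The desk-scale small-sphere radius of 4 voxels
  keeps the phantom comfortably wider than the smoothing kernel.

Two caveats about what reduced-scale results can and cannot show. First, the
*severity* of the plain Gaussian bootstrap's under-coverage grows with the
size of the boundary relative to the noise smoothness: the 40³/radius-12
sphere shows clear under-coverage (≈0.85 at N = 60 versus a nominal 0.95)
but not the collapse to ≈0.55 seen at 100³/radius-30. The direction and
ordering of the method comparison are preserved at reduced scale; the
magnitudes are not. Second, the Wild t-Bootstrap's small-$N$ coverage on the
2D circle sits one to two points *above* nominal here (≈0.97 at N = 60,
≈0.955 at N = 120, 1000 trials), consistent with published reports in which
most, but not every, 2D result fell within the binomial interval of
nominal; the corresponding acceptance check is deliberately left asserting
the strict all-sample-sizes version.

The generator emulates smooth stationary (or variance-ramped) Gaussian
noise on a rectangular domain. Real fMRI data depart from this in known
ways — non-Gaussian heavy tails, spatially varying smoothness, irregular
masks with interior holes, inter-subject registration error — so passing
coverage here validates the implementation of the method, not its
universal finite-sample behaviour on arbitrary data.

## The sd divisor

The published model treats $\sigma(s)$ as known; an implementation must pick
an estimator. The package uses the residual-dof divisor $N - p$ for
$\hat\sigma$, the unbiased-variance convention. The choice is nearly
inconsequential: the plain bootstrap is exactly invariant to it (the
critical value rescales against $\hat\sigma$), and for the studentized
variant it moves N = 60 coverage by under one point (the $t$ critical value
is scale-invariant per boundary point, so only the CS half-width
$k\hat\sigma v_w$ changes, by the factor $\sqrt{N/(N-p)}$).

## Degenerate inputs and edge conventions

* A masked voxel whose residual variance is zero up to solve roundoff
  (relative tolerance $10^{-10}$) raises an error naming the voxel — it
  signals pathological input (e.g. a constant image region), not a boundary
  case the method defines.
* An empty excursion set, or one with no in-mask boundary edge (e.g. filling
  the whole mask), is an explicit error advising a different $c$.
* Thresholds tie-break inside: $f(s) = c$ places $s$ in the excursion set
  and in each confidence set whose shifted threshold it meets.
* Interpolation weights always have a strictly positive denominator
  ($f(s_I) \ge c > f(s_O)$), guarded by an internal assertion.

## What the acceptance script recomputes

`scripts/acceptance.R` re-runs, from scratch at the reduced scales above:
the 2D circle experiment at N = 60 under the plain Gaussian bootstrap
(interpolated assessment), the 3D large-sphere analogue, and the 3D
two-sphere × {60, 120} battery under the Wild t-Bootstrap, reporting the
minimum and maximum combined-assessment coverage across the battery. All
quantities are empirical coverages in percent, computed by
`run_simulation()` at runtime from the `--seed` argument.
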
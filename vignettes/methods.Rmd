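---
title: "Optimal multidimensional population codes: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal multidimensional population codes: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effcode)
```

## The model

A population of `N` sensory neurons encodes a 2-D stimulus `s = (s1, s2)`
drawn from an environmental distribution `p(s)`. Each neuron fires as an
independent Poisson process whose rate is given by a tuning curve
`h_n(s)`; the uniform reference population places identical unimodal
(Gaussian) kernels on a uniform lattice in a *sensory space* `ŝ`, so
that the summed response approximately tiles the space (`Σ_n h_n ≈
const`). Heterogeneity is introduced by exactly two smooth functions: a
displacement field `f(s)` that warps stimulus space into sensory space,

    ŝ = s + f(s),

and a gain `g(s)` that scales response magnitude. Under an efficient
coding objective — maximize the Fisher-information lower bound on the
mutual information between stimulus and response, subject to a fixed
neuron budget `∫ d(s) ds = N` and spike budget `∫ p(s) g(s) ds = R` —
the optimal allocation is

    d(s) = N p(s),   g(s) = R,

i.e. neuronal density proportional to stimulus probability and constant
gain, in any number of dimensions. In 1-D the optimal warp is the scaled
cumulative of `p`; in higher dimensions a cumulative does not exist for
non-separable distributions, but a smooth warp with the required
Jacobian determinant can always be written as the gradient of a scalar
*encoding potential* `v(s)` (a smooth displacement field between two
densities is conservative). The density-remapping constraint becomes a
Monge–Ampère-type equation,

    p(s) / u(s) = det(I + H(v)),

with `u` the uniform reference density and `H` the Hessian. The
`potential_solver` module solves this equation numerically; everything
else (populations, Fisher fields, slice experiments) consumes its
solution.

## Numerical scheme

**Discretization.** The domain is the square `[-1, 1]^2` sampled on a
cell-centered lattice with inclusive endpoints (default 65 × 65).
Integrals are Riemann sums with cell-area weights. Derivatives use fixed
separable pairs: 3-tap centered stencils `[-1 0 1]/2h` and `[1 -2 1]/h²`
combined with a `[1 2 1]/4` prefilter along the orthogonal axis. The
pairs are second-order accurate and exact on quadratics, and — the
property that matters most here — every operator annihilates the
checkerboard mode. During development we found that unfiltered centered
stencils let the optimizer converge to a checkerboard-contaminated
minimizer with a large constant residual offset, because the discrete
integration-by-parts identity for the `det H` term fails at high
frequencies; sharing one parity-killing prefilter across all operators
removes the failure mode. The boundary band (one cell, the filter
half-width) replicates the adjacent interior values, so the normal
derivative of the potential — and hence the normal displacement — is
exactly zero at the boundary and probability mass cannot leave the
domain.

**Interior region and target ratio.** The square boundary would imprint
itself on the solution, so the stimulus density is only imposed inside
an interior region (default: circle of radius 0.9), outside of which
`p` is blended into `u` with a cosine ramp of width 0.05 so both
densities agree near the boundary without discontinuities. The blended
ratio is band-limited by one pass of the same prefilter (an `O(h²)`
perturbation, the order of the scheme itself — without it the ramp's
near-Nyquist content is unreachable and the residual plateaus) and
rescaled to exact unit mean, the discrete solvability condition for a
map with zero normal boundary displacement. Analyses are restricted to
the central 65% crop (`|s_i| ≤ 0.65`) to exclude boundary artifacts.

**Optimization.** The potential minimizes the accumulated squared
residual of the expanded determinant equation over interior cells, by
Polak–Ribière nonlinear conjugate gradients with an Armijo backtracking
line search (accepted objective values are monotone), wrapped in a
coarse-to-fine multigrid scheme (default 33² → 65²; the coarse solution
is bilinearly upsampled in physical coordinates, which preserves
gradients). The free variables are the interior values; the boundary
band moves as tied groups. Convergence is fast because of a spectral
preconditioner: at `v = 0` the Gauss–Newton Hessian in the free
parametrization is `A²` with `A = T⊗P + P⊗T`, where `T` is the 1-D
Neumann second-difference operator and `P` the prefilter; since
`P = I + (h²/4) T` exactly, both are diagonal in `T`'s eigenbasis and
`A²` can be inverted mode-by-mode. Modes near Nyquist in both axes are
projected out of the preconditioned gradient rather than amplified —
they are invisible to the filtered operators, and amplifying them
pollutes the potential without reducing the objective. A level stops
when the interior RMS residual falls below `rms_tol` (default `1e-4` on
the unit-mean ratio scale) or the relative objective decrease stalls;
the iteration cap is reported via the `converged` attribute. Typical
solves reach RMS residuals of `2–3 × 10⁻⁴` in about a second.

**Inversion.** Visualization and per-neuron analyses need pre-images of
sensory-space points (`s` with `s + f(s) = ŝ`). Plain fixed-point
iteration diverges where the warp compresses strongly (`|∂f| ≥ 1`), so
the package uses damped Newton iteration with the interpolated Jacobian,
per point, exact to `1e-6` stimulus units anywhere in the domain
(`invert_at`); the gridded inverse field is built the same way.

## Populations and measurements

Tuning curves are isotropic Gaussians in sensory space composed with the
forward warp, `h_n(s) = g · h(s + f(s) - ŝ_n)`, on a hexagonal lattice
with a one-spacing margin beyond the domain (so warped boundary neurons
do not dig tiling dips into the crop). Defaults follow the published
examples: tuning width `σ = 0.05`; lattice spacing `0.2` (4σ) for
visualization, but **2σ for every quantitative analysis** — at spacing
4σ a 2-D hexagonal Gaussian population simply does not tile (summed-rate
coefficient of variation ≈ 48%, versus 0.3% at 2σ), and the source
analyses themselves halved the spacing for exactly this reason when
measuring Fisher information. The spike budget `R` is enforced by
scaling the constant gain so the expected population rate under `p`
equals `R`.

Fisher information is computed exactly from the Poisson form
`F_ij = Σ_n (∂_i h_n)(∂_j h_n)/h_n` with centered differences at grid
resolution (enforced: at least 4 samples per tuning σ; rates below
`1e-9` of peak are excluded from the sum to avoid 0/0), and
approximately from the smooth-warp formula `det F ≈ g^k det(I+J)^2 U`,
where `U` — the uniform population's Fisher level — is *measured* as the
median of `det F` over the crop, not assumed. The mutual-information
lower bound uses the k-dimensional extension with `det F` and
`(2πe)^k`, evaluated over the crop with `p` renormalized there; the 1-D
statement in the source is extended to k-D on the grounds that the
Fisher determinant bounds the determinant of an unbiased estimator's
covariance.

## The randomized slice experiment

Each replicate draws a zero-centered bivariate Gaussian stimulus
distribution (orientation uniform on `[0, π)`, major/minor σ uniform on
`[0.1, 0.4]`), solves for its optimal potential at 65², warps a
population with tuning σ drawn uniformly from `[0.03, 0.07]` (spacing
2σ), picks a random slice (axis by fair coin, held value uniform within
the crop), evaluates all tuning curves on 2001 points across the crop,
retains neurons whose maximum normalized response within the slice is at
least 0.2, samples 25 of them, and measures per neuron the gain (maximum
response), the FWHM (linear interpolation of the half-maximum crossings
nearest the peak; curves peaking at the slice edge or missing a crossing
are excluded), and the joint probability `p(s)` at the neuron's peak
within the slice (free-axis argmax, held axis at the slice value — the
source does not state which location it used; this reading is the
package default). Pearson correlations of sharpness (1/FWHM) and gain
against probability are collected per replicate; medians are tested
against zero with a two-sided Wilcoxon signed-rank test. The default
test scale is 100 replicates (the published study used 500; medians are
stable well below 100), and one seed drives the entire experiment, so
repeated runs are byte-identical.

## What the synthetic world does and does not establish

All inputs are parametric densities — there is no empirical
natural-scene data anywhere. A green acceptance suite establishes that
the numerical pipeline reproduces the *internal* predictions of the
theory (density ∝ probability, constant gain, `√det F ∝ p`,
sharpness–probability correlation ≈ 1, gain–probability correlation
≈ 0), not that biological populations obey them. Known limitations:

* The solver is restricted to square 2-D domains; uniqueness of the
  potential is not guaranteed (none of the tested densities showed
  multiple minima, matching the source's experience), but determinism
  given a configuration is the tested contract.
* The smooth-warp Fisher approximation degrades when displacement or
  gain vary within a tuning width; the package demonstrates this
  failure deliberately (a gain grating with wavelength ≈ 3σ drives the
  approximation error above 50% RMS).
* Kernel support crossing the domain boundary is not modeled; analyses
  stop at the 65% crop.
* The non-separable example's bandwidth profile
  `σ(s₂) = 0.1 + 0.15 (1 + cos π s₂)/2` is an explicit stand-in chosen
  to be smooth and bounded away from zero; the source never states its
  functional form.
* On the truncated domain, kurtosis comparisons for the
  generalized-Gaussian example with scale 0.75 are uninformative (the
  tails are cut at ≈ 1.1 sd), so leptokurtosis is asserted for the
  kernel family itself against the closed-form gamma expression.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `resolution` | 65 | cells/axis | resolves σ ≥ 0.03 warps; replicate solves ≈ 1 s |
| `levels` | 2 | — | 33² initialization suffices below 129² targets |
| `rms_tol` | 1e-4 | unit-mean ratio | an order below the 1e-3 acceptance level |
| `interior_radius` | 0.9 | × extent | largest circle clearing the boundary band |
| `ramp` | 0.05 | × extent | narrowest smooth blend the prefilter resolves |
| `crop_fraction` | 0.65 | × extent | published analysis crop |
| tuning `sigma` | 0.05 | stimulus units | published example width |
| lattice spacing | 2σ (analysis) | stimulus units | tiling CoV < 1%; 4σ only for sparse visualization |
| `min_response` | 0.2 | × peak | published slice retention rule |
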
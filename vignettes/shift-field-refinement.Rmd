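---
title: "Shift-field refinement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-field refinement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftfieldr)
```

## The problem

Macromolecular crystals rarely diffract to a resolution at which individual
atoms are resolved, so refining a model atom-by-atom against the data is an
under-determined problem that conventional programs stabilize with chemical
restraints. Restraints couple neighbouring atoms and slow convergence, and
they presuppose a chemically sensible model. Shift-field refinement takes a
different route: the refinable parameters are attached not to atoms but to
the grid points of the electron-density map itself. At every grid point we
ask what local change in position (`x, y, z`), isotropic displacement
(`U_iso`, where `B = 8*pi^2*U`) and a constant density offset would best
explain the current difference map within a surrounding sphere. Because the
spheres of neighbouring grid points overlap heavily, the resulting shifts
are spatially correlated and the *effective* number of free parameters is
controlled by the sphere radius, not by the grid: larger radii give fewer
effective parameters, which is what low-resolution data need.

## The estimator

Let `rho` be the current model map and `D` the difference map. For each
refinable parameter `p` we form the derivative map `X_p = d rho / d p` by
reciprocal-space multiplication: `2*pi*i*h_j` for the fractional positional
parameters and `-2*pi^2*|s|^2` for `U_iso`, plus an all-ones constant
column. The sign convention is the *parameter* derivative — for a small
shift `dp` of the underlying model, `rho_new ~ rho + X_p * dp` — so the
solved shifts are corrective when added to model parameters (this also
fixes the sign of the positional columns as the negative of the spatial
density gradient).

At grid point `q`, weighted least squares over the surrounding sphere gives

    Delta(q) = (X' W X)^-1 X' W Y

where the rows of `X` and `Y` run over the grid points inside the sphere,
and `W = diag(w_k * g(r_k))` combines the per-voxel weight map `w` with
the radial kernel `g`. Every entry of the normal matrix and right-hand
side is a sum of a product map over a sphere, i.e. a convolution:

    A_ij(q) = [(w * X_i * X_j) (*) g](q),    b_i(q) = [(w * X_i * D) (*) g](q)

computed once per unique term as an FFT product, so the cost is independent
of the sphere radius. With `n` active columns this is `n(n+1)/2 + n`
convolution passes — 20 in full five-parameter mode — followed by a small
`n x n` solve per voxel. `shift_field_direct()` implements the same
estimator by literal sphere enumeration and serves as the independent
cross-check of the convolution route in the test suite.

The resulting `Delta` maps are the shift field. `apply_to_model()`
trilinearly interpolates each component at every atom and increments the
atom's parameters; `morph_map()` instead resamples a density map by
pull-back, `out(q) = in(q - Delta(q))`, which needs no atomic model at
all. The constant-column shift is solved but discarded — its only job is
to absorb slowly varying offsets (e.g. from missing low-resolution terms)
so they do not contaminate the other columns.

## Parameters that matter

* **`r0`** (angstrom) — the kernel radius, the method's central dial.
  Small radii resolve fine, independent corrections; large radii force
  coordinated shifts and suit low resolution. `radius_sweep()` measures
  the best radius for a data set; `r0_from_resolution()` provides a linear
  heuristic `r0 = slope * d_min + intercept`, clipped into [1.5, 8]. The
  default coefficients (1, 1) pass through `r0 = 3` at 2 angstrom
  resolution and are a placeholder: they are configuration to be refit by
  sweeping, not a fitted constant of the package.
* **Kernel form** — `g(r) = 1` (step), `1 - r/r0` (linear) or
  `1 - (r/r0)^2` (quadratic), zero beyond `r0`. Quadratic is the default;
  a smooth taper downweights the sphere edge, and scaling `g` by any
  positive constant provably leaves the shifts unchanged.
* **Mask** — `"model"` weights only voxels within 2.5 angstrom of an
  atomic centre (binary weights; soft masks are accepted by the solver but
  not generated), excluding unmodelled solvent from the regression.
  `"uniform"` weights everything.
* **Mode** — `u_only` (n = 2) reproduces the classic displacement-parameter
  experiment; `positions_only` (n = 4) drives map morphing;
  `full` (n = 5) refines everything at once.
* **`ridge` and the condition cap** — per-voxel normal matrices in empty
  solvent can be near-singular. A relative ridge (`1e-6 * trace(A)/n` on
  the diagonal) stabilizes borderline voxels; anything with condition
  number above `1e8` gets zero shifts and a singular flag. Zeroing is
  deliberate: an unflagged garbage shift would corrupt morphing, while a
  zero shift is merely inert.
* **`damping`** — a step-size factor on applied shifts, default 1 (direct
  application). Exposed because strongly discontinuous fields can distort
  a model; damping plus extra cycles is the built-in mitigation, and
  stereochemical regularization after morphing is out of scope.
* **`u_floor = 0.01`** square angstrom — per-voxel `U` shifts on noisy
  data can drive atomic `U` negative; the clamp keeps the Gaussian model
  defined.

## The density engine behind the driver

`run_refinement()` iterates: calculated structure factors from the model,
overall scaling against the observations, R and free R, a difference map
from work reflections, gradient fields, the shift-field solve, and shift
application. Three deliberate simplifications relative to a production
refinement program:

* **Gaussian atoms.** Each atom is a single normalized Gaussian of weight
  `Z` (electron count) and variance `U_iso`, truncated at
  `max(3*sqrt(U) + 1, 2.5)` angstrom (< 0.2% mass loss). This is not a
  production scattering model (no multi-term form factors, no solvent),
  but it preserves exactly the properties the method exercises —
  Fourier-differentiability and the `exp(-2*pi^2*U*|s|^2)` dependence on
  `U` — and it has an exact analytic transform (`sf_direct()`), which the
  tests use as an oracle against the FFT route.
* **Plain difference coefficients.** Work-reflection coefficients
  `(|Fobs| - k_s |Fcalc|) * exp(i*phi_calc)` with optional `1/sigma^2`
  weighting, multiplier 1. Likelihood (sigma-A) weighting is the
  production-grade alternative and is deliberately not implemented.
* **Two-parameter scaling.** `k` and an overall `dU` fitted log-linearly
  on work reflections; the applied scale is `k * exp(-2*pi^2*dU*|s|^2)`.
  This reproduces the useful degeneracy that a uniform error in all `U`
  values is absorbed by the scale (so results are independent of the
  constant used in a constant-U reset), without bulk-solvent or
  anisotropic terms.

One convention is worth stating: the difference map is on the observed
amplitude scale, so the driver also scales the calculated coefficients by
`k_s` before differentiating. Difference map and design matrix therefore
share one scale and solved shifts come out directly in model-parameter
units.

Everything is P1: space-group symmetry is out of scope, and real
symmetric data must be expanded to P1 upstream. Fractional coordinates are
primary throughout; angstroms appear only in radii and reports.

## What the synthetic crystals emulate — and what they do not

`make_toy_structure()` packs C/N/O/S atoms (minimum separation 1.5
angstrom) randomly, on a helical path with ~3.8 angstrom consecutive
spacing, or as two separated domains; per-atom `U` is uniform in a chosen
range (default 0.1-0.4 square angstrom, typical of well-ordered
structures at ~2 angstrom). `simulate_observations()` applies
multiplicative Gaussian amplitude noise (`1 + eps`, `eps` clamped at 3
sigma, floored at 0.01) and assigns free flags; `perturb_model()` creates
the refinement problems (constant-U reset to 0.5, positional jitter,
rigid single-domain shifts). The preset library
(`inst/extdata/presets.yaml`) spans 1.5-3.5 angstrom resolution with 2%
noise at the working points and 12-50 atoms in 18-30 angstrom cells —
sizes chosen so the whole suite and the acceptance script run in minutes
on one core while keeping thousands of reflections per crystal.

Passing tests on these crystals show that the estimator, its convolution
implementation and the iterative protocol are correct and well behaved.
They do not show robustness to the things real data add: bulk solvent,
model incompleteness, realistic error models (Wilson/intensity
statistics), space-group symmetry or radiation damage. The one
systematic deviation from practice is that the difference maps come from
this package's own plain density engine rather than a likelihood-weighted
refinement program.

## Numerical choices and degenerate inputs

* Fourier convention: `F(h) = integral rho exp(+2*pi*i*h.x) dV`, inverse
  carries `1/V`; `F(000)` is the map integral (electron count). Parseval
  then reads `sum_fullsphere |F|^2 = (V^2/N) * sum rho^2`.
* Grids are per-axis smallest 2,3,5-smooth counts meeting spacing
  `d_min/(2*oversample)`; default `oversample = 1.5` (spacing `d_min/3`).
  Synthesis onto a grid that cannot hold the band limit raises an
  aliasing error rather than wrapping indices.
* Minimum-image distances (kernel, masks, separation checks) use the
  wrapped fractional offset; exact for orthorhombic cells, and an
  approximation only for strongly sheared cells, which the toy generators
  never produce.
* The kernel must exceed one voxel spacing (else the sphere can be empty)
  and stay below half the shortest cell edge (else it overlaps itself
  through the periodic wrap); both violations are errors, not warnings.
* Ties and flags: voxels failing the condition cap, or whose explicit
  regression is under-determined (fewer usable points than columns, zero
  weights), carry zero shifts and `singular = TRUE`; counts are reported
  per cycle in the refinement statistics.
* Determinism: every stochastic step takes an explicit integer seed and
  restores the caller's RNG state; identical configuration and seeds give
  bit-identical results.

## A known sharp edge: what amplitude data cannot see

In P1 a rigid translation of the *entire* model changes only phases, not
amplitudes, so the difference map built from amplitude residuals with
model phases is identically zero and positional refinement (correctly)
does nothing. Recovery experiments therefore perturb non-uniformly — a
shifted domain, or per-atom jitter — and positional accuracy is judged
after removing the free global translation. The same freedom means a
refined model can drift bodily relative to the ground truth while fitting
the data essentially perfectly.

## A worked miniature

```{r example, fig.width = 5, fig.height = 3.2}
fx <- make_fixture("small_noisy", seed = 3)
cfg <- refine_config(d_min = 2.0, mode = "u_only", radius_a = 3, n_cycles = 3)
res <- run_refinement(fx$start, fx$fobs, cfg)
glance(res)
cor(res$model$u_iso, fx$truth$u_iso, method = "spearman")
autoplot(res)
```

The constant-U start explains the data poorly; most of the R-factor
improvement arrives in the first cycle, and the refined per-atom `U`
values rank-order the true ones closely even though no restraint ever
connected the atoms.

## Limitations

Anisotropic displacement parameters (six-column fields), occupancy
shifts, non-spherical kernels, space-group symmetry, likelihood
weighting, bulk solvent and post-morph regularization are all out of
scope. `morph_map()` applies positional components only; transferring
`U` shifts onto a map is a genuinely harder problem and is deliberately
not attempted.
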
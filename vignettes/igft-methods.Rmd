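---
title: "Occupancy fluctuations and cavity solvation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy fluctuations and cavity solvation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igft)
```

## The problem

Dissolving a hard, non-polar solute in a liquid costs the reversible work of
emptying a solute-shaped cavity, and that work is fixed by the solvent's
spontaneous density fluctuations: `beta mu_ex = -log p_0`, where `p_0` is the
probability that an observation volume of the solute's size and shape is
found empty.  In small volumes these fluctuations are close to Gaussian, so
the whole problem reduces to knowing the mean occupancy `<n>` and the
normalized variance `chi = var(n)/<n>` of the observation volume.

`igft` implements an analytic model for `chi(R)` of spherical volumes that
needs only three inputs: the solvent number density `rho_w(T)`, the
isothermal compressibility `kappa_T(T)`, and one molecular length, the
effective solvent diameter `d_ww`.  Everything else — occupancy
distributions, hydration free energies, and their full temperature
decomposition — follows from those inputs.

## The interpolated variance model

Two limits of `chi(R)` are exact:

* **Microscopic.** For `R <= d_ww/2` at most one solvent center fits in the
  volume, pair correlations cannot contribute, and
  `chi(R) = 1 - (4 pi / 3) R^3 rho_w`.
* **Macroscopic.** As `R -> infinity` the fluctuation integral reduces to
  the Kirkwood–Buff compressibility value
  `chi_inf = k_B T rho_w kappa_T` (dimensionless).

Between the two, `chi(R)` for a *sphere* admits a Laurent expansion in `1/R`
whose quadratic term vanishes identically — a geometric property of the
spherical overlap kernel.  The model therefore bridges the limits with

```
chi(R) = chi_inf + sigma1 / R + sigma3 / R^3       (R > d_ww/2)
```

where `sigma1` and `sigma3` are fixed — not fitted to data — by requiring
value and slope continuity with the exact microscopic branch at
`R = d_ww/2`.  Those two conditions form a 2×2 linear system with the
closed-form solution implemented in `solve_chi_coefficients()`; the
constructor `chi_model()` verifies both continuity residuals (1e-12 on the
value, 1e-8 relative on the slope) on every build.  We solve the system
exactly rather than least-squares fitting it because two constraints
determine two unknowns uniquely.

```{r}
sp <- state_point(T = 298.15, rho_w = 0.0334, kappa_T = 4.5e-5)
m <- chi_model(sp, d_ww = 2.647)
m
chi(c(0, 1, 2.647 / 2, 3.3, 100), m)
```

With ambient-water-like inputs `chi` decays monotonically from 1 at `R = 0`
to `chi_inf ~ 0.062`.  Known limitation: the model carries no structural
information beyond `d_ww`, so it cannot reproduce the packing oscillation
in `chi` near `R ~ 3` Å, nor the shallow high-temperature minimum in
`chi(R)` that appears in hot water unless `d_ww` is allowed to grow with
temperature — we keep `d_ww` temperature-independent as a deliberate
single-parameter design.

## Tunable parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `d_ww` | Å | 2.647 | distance below which pair correlations do not contribute; roughly where the solvent pair correlation function first crosses 1 |
| `rho_w` | Å⁻³ | user | solvent number density |
| `kappa_T` | bar⁻¹ | user | isothermal compressibility |
| `T0` | K | 298.15 | reference temperature of the thermodynamic fit |

All chemical potentials are computed and stored as dimensionless `beta mu`;
conversion to kJ/mol happens only at output (`units = "kJ/mol"`), using
`k_B` fixed at 1.380649e-23 J/K (once, converted to bar·Å³/K so that
`chi_inf` is dimensionless without a unit library).

## From fluctuations to free energies

Two occupancy models convert `(<n>, chi)` into `p_0`:

* `mu_excess()` — the **continuous Gaussian**:
  `beta mu = <n>/(2 chi) + log(2 pi <n> chi)/2`, identical to
  `-log` of the normal density at `n = 0`.  The Gaussian leaks probability
  to `n < 0`; `negative_mass_diagnostic()` reports (never subtracts) that
  mass, which is negligible for atomic-sized cavities.
* `fit_maxent()` — the **discrete two-moment maximum-entropy model**
  `p_n = exp(lambda0 + lambda1 n + lambda2 n^2)` on the non-negative
  integers, fitted by damped Newton iteration on `(lambda1, lambda2)`
  (Jacobian = moment covariance; initialization from the matching Gaussian,
  `lambda1 = <n>/sigma^2`, `lambda2 = -1/(2 sigma^2)`; backtracking line
  search on the residual norm).  Support is capped at
  `max(50, <n> + 10 sigma)`, which keeps truncation below the 1e-12 solver
  tolerance; only two moment constraints are used.

For sub-diameter solutes (`R < d_ww/2`) the empty-volume probability is
exact, `p_0 = 1 - (4 pi/3) R^3 rho_w`, and `mu_exact_small()` /
`mu_igft()` use it directly.  At the seam `R = d_ww/2` the Gaussian and
exact branches need not coincide; we use the Gaussian branch for all
`R >= d_ww/2` and note that for ambient-water inputs the two differ by
about 2% (0.008 k_BT) there.

## Temperature decomposition

`mu_vs_T()` rebuilds the model at each temperature from an equation-of-state
table (`eos_table`, monotonicity-preserving cubic interpolation by default —
chosen over ordinary splines to avoid overshoot where `kappa_T` grows
steeply).  The resulting `mu(T)` is fitted (`fit_thermo()`, unweighted
linear least squares) to the five-parameter form

```
mu(T) = a1 + a2 (T - T0) + a3 [T log(T/T0) - (T - T0)]
        + a4 (T - T0)^2 + a5 (T - T0)^3
```

chosen so that the hydration heat capacity is quadratic in temperature,
`c = -T d2mu/dT2 = -a3 - 2 a4 T - 6 a5 T (T - T0)`, appropriate for a heat
capacity that decreases at low temperature and rises again toward the hot
liquid.  Entropy and enthalpy follow from closed-form derivatives
(`s = -dmu/dT`, `h = mu + T s`), so `mu = h - T s` holds identically.
Derivatives are taken through the fit rather than by differentiating the
theory directly; the test suite cross-checks both routes by finite
differences.  Two characteristic temperatures are solved for:

* `solubility_minimum_T()` — root of `h(T) = 0` (Brent, 0.01 K), where the
  Ostwald solubility `K_eq = exp(-beta mu)` is minimal;
* `entropy_convergence_T()` — root over `T` of `ds/dR = 0`, evaluated with
  a centered `dR = 0.01` Å difference of entropies from two fits (the
  analytic theory is smooth, so this truncation sits far below the 0.1 K
  root tolerance); and `t_conv_point_solute()`, the exact point-solute
  limit `T alpha(T) = 1` with `alpha = -d log rho/dT` from the table.

## Validation by synthetic fluids

Because the theory's claims are statistical, the package ships brute-force
samplers and desk-scale fluids with known answers:

* `generate_ideal_gas()` draws the particle count of each configuration
  from Poisson(`rho V`), so any probe in any configuration has *exactly*
  Poisson occupancy (`chi = 1`): the end-to-end null of the entire
  insertion pipeline.
* `hs_monte_carlo()` is a Metropolis hard-sphere fluid (diameter 1, fcc
  start, displacement step auto-tuned toward 40% acceptance during
  equilibration only, then frozen; every emitted configuration is verified
  overlap-free).  Its macroscopic `chi` is pinned by the Carnahan–Starling
  compressibility, `(1-eta)^4 / (1 + 4 eta + 4 eta^2 - 4 eta^3 + eta^4)`.
* `sample_occupancy()` performs seeded uniform probe insertions (spheres:
  strict `<`; cuboids: half-open intervals — measure-zero boundary choices
  made for bit-reproducibility), with block-bootstrap errors over whole
  configurations because insertions within a configuration are correlated.

Sampling fixed-N configurations is not the open-ensemble the macroscopic
limit refers to: the canonical pair correlation carries the well-known
`-chi_inf/N` offset, which depresses the sampled normalized variance by
`(v/V) chi_inf` for a probe of volume `v` in a box of volume `V` (exactly
`1 - v/V` for a fixed-N ideal gas).  `chi_infinity_from_configs()` builds
this into the estimator: it samples `chi(R)` on a radius grid and fits the
basis `{1 - v/V, 1/R, 1/R^3}` with no intercept, so the leading coefficient
*is* the open-system `chi_inf` — a finite-volume extrapolation in the
spirit of small-system Kirkwood–Buff methods.  For the `eta = 0.30`,
`N = 256` hard-sphere fluid this recovers the Carnahan–Starling value
0.098 within its statistical error.  Configurations used for large-volume
estimates are spaced 500 sweeps apart: box-scale density modes decorrelate
over thousands of single-particle sweeps, and tighter spacing leaves
bootstrap errors optimistically small (the 100-sweep default of
`hs_monte_carlo()` is adequate for solute-sized probes).

The cross-check of the fluctuation integral itself is independent of all
of this: `chi_numeric()` evaluates the one-dimensional reduction of the
double volume integral of `(g - 1)` with the sphere-overlap (lens) kernel
by refined trapezoidal quadrature (step ≤ 0.01 Å, linear interpolation of
`g`, `g = 1` assumed past the table with a warning), while `chi_step_mc()`
estimates the same quantity for a step `g` by direct 6-D Monte Carlo pair
sampling, sharing no code with the quadrature.

## The synthetic water-like equation of state

`water_like_eos()` provides the ambient-like table used in examples and
validation.  It is a closed-form emulation of a compressed liquid-water
isobar, not measured data: log-density with a linearly growing expansion
coefficient (`alpha` from 2.7e-4 K⁻¹ at 298 K to ~2.3e-3 K⁻¹ in the hot
liquid, so `T alpha = 1` is crossed near 541 K), and log-compressibility
quadratic in `T`, giving the shallow compressibility minimum near 320 K
and accelerating growth toward the hot liquid.  The table spans 260–600 K,
a compressed-liquid window; extrapolating the quintic fit far beyond the
hot end enters the convex tail of `mu(T)` where the fitted heat capacity
would turn negative, so analyses here use grids within the table.

What passing the synthetic-fluid tests does **not** show: real-water
features absent from these generators — packing oscillations in `chi(R)`,
fat low-`n` tails for nanometer cavities (the Gaussian model is known to
break down beyond roughly xenon-sized solutes), interfacial enhancement of
fluctuations near extended hydrophobic surfaces.  The cuboid profile
machinery (`chi_profile()`) measures such effects from user-supplied
configurations but the analytic model makes no claim about them.

## Numerical choices and degenerate inputs

* `interpolate_state()` refuses to extrapolate; `thermal_expansion()` falls
  back to one-sided differences at table boundaries with a warning, with
  step `min(1 K, spacing/10)`.
* `fit_maxent()` raises informative errors on non-convergence (carrying the
  last residuals) and on variances too large for a `lambda2 < 0` solution
  on finite support; `<n> = 0` returns the deterministic empty
  distribution.
* `solubility_minimum_T()`, `entropy_convergence_T()` and
  `t_conv_point_solute()` return `NA` with a `reason` attribute (not an
  error) when no root exists in range.
* `fit_thermo()` rejects grids of fewer than 5 points or spanning less
  than 100 K, where the five-term basis is ill-conditioned.
* `R = d_ww/2` belongs to the microscopic branch of `chi()`; both branches
  agree there to machine precision by construction.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script simulations are sized for a desk:
ideal-gas null at 200 configurations × 2000 insertions; hard-sphere fluid
at `N = 256`, `eta = 0.30`, 150 configurations spaced 500 sweeps after
3000 equilibration sweeps; brute-force pair sampling at 1e7 pairs per
radius; smoothness sweeps over 1000 random state points.  These choices
keep every statistical comparison at the 3-standard-error level while
running in well under an hour on one CPU.
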
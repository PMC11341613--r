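---
title: "Models and numerics behind hemorom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind hemorom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemorom)
```

`hemorom` couples a desk-scale full-order hemodynamics solver with a
non-intrusive POD--RBF surrogate for blood-stasis indices. This vignette is
the package's own account of the models, the numerical choices, and their
limits.

## The flow model and its assumptions

The full-order model is incompressible Navier--Stokes with rigid walls,
laminar flow, and blood density $\rho = 1050\,$kg/m$^3$. Rigid walls are the
standard modelling choice for the fibrillating atrium, where active wall
motion is largely lost; laminarity is justified at the Reynolds numbers the
idealized case produces (tens to hundreds). Two constitutive laws are
available:

* **Newtonian**: constant dynamic viscosity $\tilde\mu = 3.5\,$mPa$\cdot$s.
* **Casson**: a yield-stress, shear-thinning law
  $\tilde\mu(J_2) = \left[(\bar\eta^2 J_2)^{1/4} +
  (\tau_y/2)^{1/2}\right]^{2} J_2^{-1/2}$ with
  $\bar\eta = \eta/(1 - H/100)^{2.5}$ and
  $\tau_y = (0.290\, H/100)^3\,$Pa, driven by plasma viscosity $\eta$
  (Pa$\cdot$s) and hematocrit $H$ (percent).

Two Casson conventions deserve a note. First, the **outer exponent**: with
an outer exponent of $1/2$ on the bracket (a form that does appear in
print) the zero-yield-stress limit fails to reduce to a constant viscosity.
We implement the standard Casson form, whose exponent 2 recovers
$\tilde\mu \to \bar\eta$ as $\tau_y \to 0$ and hence an exactly Newtonian
fluid at $H = 0$; the other variant remains available via
`rheology_params(strict_paper = TRUE)` for comparison. Second,
**hematocrit units**: ranges like $H \in [35, 50]$ only make sense in
$(1 - H)^{2.5}$ when read as percent, so all formulas divide by 100.

The Casson viscosity diverges as $J_2 \to 0$; we evaluate it at
$\max(J_2, J_{2,\min})$ with a configurable floor $J_{2,\min} =
10^{-12}\,$s$^{-2}$, the standard regularization guaranteeing bounded
coefficients in stagnant regions.

## The idealized geometry and boundary data

The synthetic case replaces a patient atrium by a rectangular chamber
(default $4 \times 2\,$cm) with a blind rectangular pocket (default
$10 \times 4\,$mm) on the right wall: the pocket reproduces the one
mechanism that matters for stasis — a cul-de-sac sheltered from the main
through-flow, where age accumulates and washout stalls. Inlets
("pulmonary veins", default 4) are equal segments of the top wall, each
carrying the same flow rate as plug inflow; the outlet ("mitral valve") is
a segment of the bottom wall with zero-gradient velocity and a fixed
reference pressure — prescribing outlet velocities alone would leave the
pressure level undefined in a pure-Dirichlet problem.

The outlet waveform is an analytic pulse: zero flow during the closed phase
$t < 0.4\,T$ and a $\sin^2$ bump afterwards, $C^1$-periodic with period
$T = 1.07\,$s, integrating to a configurable stroke volume (default
$2\times10^{-5}\,$m$^2$ per unit depth, which keeps peak velocities near
$10^{-2}\,$m/s and the flow laminar at desk scale). Only the period, the
opening phase near $0.4\,T$, and the linear scaling by the cardiac-output
factor $f$ are physiologically anchored; the pulse shape and stroke volume
are package choices, configurable in `case_config()`. The scaling contract
$Q(t; f) = f\,Q(t; 1)$ is exact by construction.

What the generator does **not** emulate: three-dimensionality, the
trabeculated LAA lobes, moving walls, inlet waveform asymmetry and real
mitral regurgitation patterns. Passing tests on this geometry demonstrate
correctness of the discretizations and of the ROM machinery, not clinical
fidelity of any particular number.

## Discretization

The mesh is uniform Cartesian (squares of side $h$), so faces are
orthogonal and two-point normal gradients are exact. The flow stepper is an
incremental pressure-projection scheme with implicit Euler in time:

1. implicit momentum predictor with upwind convection (matrix) plus a
   deferred second-order linear-upwind correction (right-hand side), lagged
   mass fluxes, and a Picard-lagged effective viscosity — one viscosity
   update per step keeps every step linear;
2. Rhie--Chow interpolation of face fluxes (suppresses collocated-grid
   pressure checkerboarding);
3. a pressure correction solved with a pre-factorized sparse Cholesky (the
   operator is constant in time up to the $\Delta t/\rho$ scale), after
   which face fluxes are discretely divergence-free.

The time step adapts to a maximum cell Courant number of 0.8 under a cap
$\Delta t_{\max} = 0.01\,$s, subcycling between snapshot instants and
landing on them exactly; snapshots are collected on the uniform schedule
$t_i = i\,\Delta t$, giving $107$ per cycle at the defaults. Integration
always starts from rest, and the final of `n_cycles` cycles is collected,
downstream of the initial transient. Steady fixtures (`run_steady()`) may
exceed the Courant cap — the implicit scheme is unconditionally stable and
only pseudo-time accuracy is sacrificed.

The explicit transpose-viscosity term $\nabla\cdot(\mu\nabla v^T)$ is
retained for both rheologies (it vanishes analytically for constant
viscosity and divergence-free fields, but only approximately so in
discrete form); sharing one momentum operator is what makes the $H = 0$
Casson run match the Newtonian run to solver precision, a property the
tests assert.

## Stasis transport

The age moments obey
$\rho\,\partial_t m_k + \rho\nabla\cdot(v\,m_k) =
\nabla\cdot(\mu_{m_k}\nabla m_k) + \rho\,k\,m_{k-1}$ with $m_0 \equiv 1$,
initial data $m_k = 0$, Dirichlet $0$ at the inlets and zero normal
gradient elsewhere; the washout solves the same equation without source,
from $\varphi = 1$. Diffusivities default to $10^{-10}$ kg/(m·s) —
advection-dominated transport. The scalars are solved **after** the flow
(segregated), against stored face fluxes; because the flow is periodic
downstream of its transient, `run_transport()` replays the stored final
cycle `n_cycles` times rather than re-running the solver, an approximation
that is exact in the periodic regime and cheap everywhere else.

Scalar convection defaults to first-order upwind: with conservative,
divergence-free fluxes the implicit upwind matrix is an M-matrix, which is
what keeps $\varphi \in [0, 1]$ — boundedness outranks formal order at desk
resolution. A `linear_upwind` option restores second-order accuracy where
boundedness is not at stake; the plug-flow oracles ($m_1 = x/u$,
$m_2 = (x/u)^2$ at steady state) use it, since the first-order scheme's
$O(h)$ inlet offset is visible on a 100-cell channel.

## Wall indices

$\mathrm{WSS} = \mathbb{T}_d \cdot n$ is evaluated per wall face from the
wall-normal velocity gradient (at a no-slip wall the tangential variation
vanishes). The default gradient is the **discretely consistent** two-point
form — the same flux the momentum diffusion uses — so the integrated wall
shear balances the driving pressure exactly at steady state; a one-sided
quadratic fit (exact for analytically prescribed parabolic profiles) is
available as `gradient = "quadratic"`. The viscosity entering the stress is
the rheology's effective viscosity at the wall strain rate.

TAWSS and OSI integrate over exactly one period of the snapshot schedule.
Two quadratures are provided: trapezoid (default) and midpoint (uniform
rectangles — the natural rule for periodic samples and exact for
piecewise-constant signals sampled at subinterval midpoints, which is how
the analytic OSI limits 0 and 0.5 are realized discretely). Faces with
identically zero shear would make the OSI ratio $0/0$; they are assigned
OSI $= 0$, the unidirectional limit.

## The reduced-order model

Snapshot matrices are assembled parameter-outer/time-inner from **raw**
fields (no mean subtraction), one matrix per variable; TAWSS and OSI are
steady and get one column per design point and a $\mu$-only interpolant.
POD uses a thin SVD directly (numerically safer than, and equivalent to,
the eigendecomposition of the snapshot correlation matrix — the
equivalence is what the Eckart--Young test checks); the numerical rank
truncates singular values below $\max(N_h, N_s)\,\epsilon_{mach}\sigma_1$.
The retained dimension is the **smallest** $L$ with cumulative energy
$\ge \varepsilon$ (strict reading of the threshold; default
$\varepsilon = 0.99$, swept over $\{0.90, 0.95, 0.99, 0.999\}$ by
`sweep_epsilon()`).

The RBF map from $(t, \mu)$ — jointly, one model per variable, not
per-time-instant models — to modal coefficients uses a thin-plate-spline
kernel by default: it is the natural partner of the degree-1 polynomial
tail (together they minimize a bending-energy seminorm) and carries no
shape parameter to tune; Gaussian and multiquadric kernels with a shape
parameter remain available. Inputs are affinely normalized to $[0,1]$ per
coordinate before kernel evaluation — seconds, Pa·s and percent differ by
orders of magnitude and would otherwise ill-condition the augmented system.
The augmented symmetric system enforces interpolation plus the moment
constraints $\sum_j w_j = 0$, $\sum_j w_j x_j = 0$; duplicate nodes and
under-determined node sets (fewer than $d + 2$) are rejected up front.
Queries outside the normalization box warn about extrapolation. Training
designs: `sample_uniform()` endpoints-included equispaced points for the
single-parameter case; `sample_lhs()` (the `lhs` package) for
$(f, \eta, H)$, seed-fixed for reproducibility. Held-out validation points
are selected **by index** in the design, mirroring standard train/test
splits of parametric snapshot sets.

Accuracy is reported as the Frobenius-norm relative error per snapshot
(time-resolved for unsteady variables, scalar for steady ones) plus its
time average.

## Manufactured snapshot family

End-to-end ROM tests need truth with known parametric structure;
`manufactured_snapshots()` provides a sum of four fixed spatial modes with
coefficients varying smoothly in $(t, f, \eta, H)$, optionally superposed
with a $1/k$-decaying series of fine modes. The smooth core is the target
for convergence studies (held-out error must at least halve when the
training design doubles); the tail gives the spectrum the slow roll-off of
genuine flow fields, so the retained dimension keeps growing at high
$\varepsilon$ while the held-out error plateaus — the characteristic
accuracy/cost pattern of POD-based surrogates.

## Problem sizes and tolerances used by the test suite

The suite runs on deliberately small cases chosen to finish a full check in
about a minute while keeping every oracle's signal well above its
tolerance: a $20 \times 10$-cell chamber with a $4\times3$-cell pocket for
pulsatile runs (1--2 cycles), a $60 \times 20$-cell channel for the
Poiseuille benchmarks (centreline-to-mean ratio $1.5 \pm 2\%$, wall shear
$\pm 3\%$), a 100-cell quasi-1-D channel for the transport oracles
($\pm 3\%$), and 120--200-dimensional synthetic snapshot families for the
ROM (POD identities at $10^{-8}$--$10^{-10}$, RBF exactness at $10^{-8}$).
Divergence after projection is accepted below $10^{-7}\,$s$^{-1}$ and is
typically at machine level.

## Known limitations

* 2-D, rigid, rectangular geometry: quantitative index values do not
  transfer to patient anatomy; orderings and convergence behaviour do.
* First-order scalar convection smears advective fronts by
  $O(\sqrt{h L})$; the washout-clearing test accounts for this.
* The RBF surrogate interpolates — extrapolation beyond the sampled
  parameter box is flagged but not controlled.
* One Picard viscosity update per step linearizes the Casson coupling;
  strongly yield-dominated regimes (far beyond physiological hematocrit)
  would need sub-iterations.
* The segregated cycle-replay for scalars assumes the flow has reached its
  periodic regime; with very few cycles the early-transient contribution
  to the age fields is approximated.
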
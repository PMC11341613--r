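# hemorom

Blood that lingers in the left atrial appendage (LAA) — a blind pouch of the
left atrium — is the dominant source of thrombi in atrial fibrillation.
Quantifying that stasis from computational fluid dynamics means solving the
incompressible Navier–Stokes equations over several cardiac cycles and
transporting stasis indicators through the flow, which is far too slow for
many-query settings (parameter studies, clinical what-if evaluation).
`hemorom` implements the full pipeline at desk scale, together with a
non-intrusive POD–RBF reduced-order model (ROM) that makes parametric
evaluation of the stasis indices essentially instantaneous, for researchers
working on cardiovascular flow surrogates.

## What it computes

**Full-order model.** A finite-volume solver for incompressible flow,

  ρ ∂ₜv + ρ ∇·(v⊗v) − ∇·𝕋 = 0,  ∇·v = 0,

with implicit-Euler time stepping, second-order upwind-biased convection and
incremental pressure projection, on an idealized 2-D atrium: a rectangular
chamber with a blind rectangular pocket (the "appendage"), several
equal-flow inlets (the "pulmonary veins") and one pulsatile outlet (the
"mitral valve") driven by a periodic waveform of period T = 1.07 s scaled by
a cardiac-output factor f ∈ [0.5, 1.5]. Blood is either Newtonian
(μ̃ = 3.5 mPa·s) or Casson:

  μ̃(J₂) = [ (η̄² J₂)^¼ + (τ_y/2)^½ ]² · J₂^-½,
  η̄ = η/(1−H/100)^2.5,  τ_y = (0.290 · H/100)³ Pa,

with plasma viscosity η and hematocrit H (percent); J₂ is the second
invariant of the strain-rate tensor. The Casson law reduces exactly to a
Newtonian fluid at H = 0.

**Stasis indices.** Segregated passive-scalar transports for the blood-age
moments m₁, m₂ (source ρ·k·m_{k−1}, fresh blood enters with zero age) and
the washout φ (initialized at 1, flushed by inflow), plus wall indices from
the wall shear stress WSS = 𝕋_d·n:

  TAWSS = (1/T) ∫₀ᵀ ‖WSS‖ dt,
  OSI = ½ [ 1 − ‖∫₀ᵀ WSS dt‖ / ∫₀ᵀ ‖WSS‖ dt ] ∈ [0, 0.5].

**Reduced-order model.** Snapshots of all five variables
Φ ∈ {m₁, m₂, φ, TAWSS, OSI} are collected over a parameter design (uniform
in f for Newtonian runs, Latin hypercube over (f, η, H) for Casson runs),
stacked into a snapshot matrix, and compressed by POD: the retained
dimension L is the smallest integer whose cumulative squared singular
values reach a threshold ε (default 99%). A radial-basis-function
interpolant with thin-plate-spline kernel and degree-1 polynomial tail —
constrained by Σwⱼ = 0 and Σwⱼxⱼ = 0 — maps (t, μ) to the modal
coefficients, so any new parameter query is reconstructed as
Φʳᵇ = Σₗ αₗ(t, μ) ℓₗ(x) without touching the solver.

## Worked example

A small Newtonian study: 6 design points over f ∈ [0.5, 1.5] on a
2 cm × 1 cm chamber with a 4 mm × 3 mm pocket, holding out the third design
point for validation.

```r
library(hemorom)

cfg <- list(
  case = case_config(chamber_length = 0.02, chamber_height = 0.01,
                     pocket_length = 0.004, pocket_width = 0.003,
                     h = 0.001, n_inlets = 2, n_cycles = 2,
                     stroke_volume = 1e-5),
  solver = solver_config(dt_snap = 1.07 / 10),
  rom = list(n_samples = 6, test_idx = 3, eps = 0.99)
)
offline <- run_offline(cfg, seed = 1)
offline
#> <rom_offline> newtonian case: 6 design points ( 5 training ), 212 cells, 10 snapshots/cycle
#>   m1       L = 1, N_s = 50
#>   m2       L = 1, N_s = 50
#>   washout  L = 1, N_s = 50
#>   TAWSS    L = 1, N_s = 5
#>   OSI      L = 1, N_s = 5

res <- run_online(offline, offline$samples[offline$test_idx, ])
for (v in names(res$errors))
  cat(sprintf("%-8s mean relative error: %.4f\n", v, attr(res$errors[[v]], "mean")))
#> m1       mean relative error: 0.0341
#> m2       mean relative error: 0.0404
#> washout  mean relative error: 0.0391
#> TAWSS    mean relative error: 0.0063
#> OSI      mean relative error: 0.0115
```

The offline phase ran the pulsatile solver at each design point, advanced
the three stasis scalars over the stored velocity snapshots, computed
TAWSS/OSI on the wall, and fitted one POD basis + RBF map per variable (a
single mode suffices at this toy resolution — the five parametric runs are
strongly correlated). The online call evaluated the surrogate at the
held-out cardiac-output factor f = 0.9 and compared it against the stored
full-order truth: the time-dependent age and washout fields are reproduced
to ~3–4% and the steady wall indices to ~1%, without re-running the solver.

`tidy()`/`glance()` summarize fitted bases and RBF maps, `autoplot()` draws
scree and error-trace plots, `plot_field()` renders any cell field on the
chamber-and-pocket geometry, and `sweep_epsilon()` reports the
accuracy/cost trade-off across energy thresholds. A command-line wrapper
with verbs `generate-case`, `run-offline`, `run-online`, `sweep-epsilon`
and `report` lives at `inst/cli/hemorom.R`.

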
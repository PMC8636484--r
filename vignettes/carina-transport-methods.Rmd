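---
title: "Modelling circulating tumour cell transport at vessel bifurcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circulating tumour cell transport at vessel bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(carinaflow)
```

## The problem

When a large vessel (millimetre calibre) splits into two daughters, the
dividing streamline terminates on the apex of the bifurcation — the *carina*
— at a stagnation point. Flow speeds in a pocket around that apex are orders
of magnitude below the bulk velocity. A circulating tumour cell (CTC) whose
streamline passes close to the apex therefore spends an unusually long time
within reach of the endothelium, which is the physical precondition for
adhesion and, eventually, metastatic arrest at large-vessel branch points.

`carinaflow` implements this haemodynamic model end to end: a parametric
planar Y-bifurcation, a steady incompressible laminar Navier–Stokes solve, a
one-way-coupled Lagrangian tracker for rigid spherical CTC analogues under
Schiller–Naumann drag and gravity, and metrics for the carina observables —
low-velocity area, residence time, and the fraction of trajectories that
approach the apex — together with bifurcation-angle sweeps, carrier-fluid
viscosity sweeps and a mesh-independence harness.

## The model

**Flow.** Steady incompressible Navier–Stokes:
$\nabla \cdot \vec v = 0$, $\rho (\vec v \cdot \nabla)\vec v = -\nabla p +
\mu \Delta \vec v$. The reference configuration is a vessel of 2 mm calibre
carrying 3 mL/min with zero-pressure outlets; with media viscosities of
1.46–2.29 mPa·s the Reynolds number stays between about 17 and 27 — firmly
laminar (`channel_reynolds()` reports it against the semicircular duct
section via the hydraulic diameter $4A/P \approx 1.22$ mm).

**Particles.** CTC analogues are rigid spheres, diameter $D_p = 14\ \mu m$,
density 1.05 g/mL, $n = 20{,}000$ per run, moved by drag
$\vec F_d = \tfrac12 C_d \rho A_p |\vec v_s| \vec v_s$ with the
Schiller–Naumann coefficient
$C_d = \tfrac{24}{Re_p}\left(1 + 0.15\,Re_p^{0.687}\right)$,
$Re_p = \rho |\vec v_s| D_p / \mu$, and by gravity $\vec F_g = m_p \vec g$
(optionally buoyancy-corrected). The slip velocity is
$\vec v_s = \vec v_{fluid} - \vec v_{particle}$, so drag relaxes the particle
towards the local flow. Coupling is one-way: 20,000 cells in a millilitre-
scale volume do not alter the flow.

## Dimensionality: the 2-D mid-plane model

The physical device has a semicircular cross-section; this package solves the
2-D mid-plane problem with channel width equal to the calibre. The 2-D flow
rate is chosen so the mid-plane mean velocity equals the 3-D bulk velocity
$\bar v = Q/A_{semicircle} \approx 31.8$ mm/s, which preserves the Reynolds
number and the velocity scale. Regime diagnostics (channel Reynolds number)
are still evaluated on the true semicircular section.

The planar approximation preserves the *qualitative* claims — existence of
the carina low-velocity pocket, its growth with opening angle and with
viscosity — but changes one quantitative observable, discussed under
*Known limitations* below.

## Numerical scheme

* **Grid.** A uniform marker-and-cell (MAC) staggered grid masked by the
  Y-outline: pressure at cell centres, velocities on faces. The spacing is
  snapped so an even number of cells spans the calibre, putting the parent
  walls and the inlet plane exactly on faces and making the grid
  mirror-symmetric about the axis (mask and face tags are symmetrised
  explicitly, so the discrete field is symmetric to machine precision:
  the 50/50 outlet split is exact).
* **Scheme.** Central differencing for convection and diffusion, marched in
  pseudo-time with an incremental pressure projection; the Poisson operator
  is factorised once per mesh with a sparse Cholesky (CHOLMOD) and reused
  every step. Cell-Reynolds numbers are ~3 at the default resolution, where
  central convection is stable and adds no artificial viscosity — essential,
  since the viscosity sweep differences are the signal. Each solve is warm-
  started from a coarsened solve (`continuation`), which cuts fine-grid
  iterations several-fold.
* **Convergence.** The monitor is the maximum velocity change per unit
  pseudo-time, normalised by the convective acceleration scale
  $\bar v^2 / w$; the default tolerance is $10^{-5}$. Mass conservation is
  enforced to machine precision by the projection (boundary-flux audits in
  the tests bound it at 0.5 %).
* **Oblique walls** are staircase-masked. Wall proximity for particles is
  therefore measured against the *discrete* staircase boundary (where the
  numerical velocity actually vanishes), computed exactly near walls and
  blended with the exact-outline distance farther away.

### The carina refinement patch

Every carina observable lives inside the stagnation boundary layer at the
apex, of thickness $\delta \sim \sqrt{\nu/k} \approx 100\ \mu m$ ($k$ the
apex strain rate) — comparable to an affordable global cell. The pipeline
therefore embeds a rectangular refinement patch (default: half-width 0.45 mm,
cell size 1/8 of the global grid, i.e. ~8 µm) centred on the apex: velocity
Dirichlet data on the patch rim are interpolated from the converged global
solve, diffusion is integrated implicitly (backward Euler, prefactored
Helmholtz operators) so the fine grid is not viscously time-step-limited, and
the all-Neumann pressure problem is regularised. Tracking and near-apex
metrics automatically sample the patch where it exists. Near-apex centreline
speeds drop by ~2.5× relative to the unpatched global grid, and the carina
metrics are stable under doubling the patch resolution or widening the patch
(fractions change by < 3 %).

## Particle integrator

The momentum relaxation time $\tau_p = \rho_p D_p^2 / 18\mu \approx 8\ \mu s$
is four orders of magnitude below the convective time scale, which makes
explicit schemes hopelessly stiff. Each step therefore freezes the fluid
velocity (sampled at the half-step position) and the Schiller–Naumann factor
and integrates the resulting linear drag equation *exactly*; the update is
unconditionally stable, exact in uniform flow, and second-order along curved
pathlines (verified against a fine-step reference in a straining field).
The time step defaults to half a cell-crossing time.

**Wall interaction.** Contact is declared within half a particle diameter of
the wall. Two behaviours are available:

* `wall_mode = "slide"` (default): the contact is impermeable — the particle
  is projected back to the clearance surface along the wall-distance gradient
  and its inward normal velocity is dropped; every contact is counted
  (`n_wall_touch`, `touch_in_region`). Rationale: on a smooth no-slip wall a
  drag-dominated particle follows streamlines that parallel the wall, so
  grazing is not arrest; on a staircase-masked grid a literal freeze-on-
  contact rule over-triggers along oblique walls (a quarter of all particles
  froze mid-branch in testing — unphysical against perfusion experiments in
  which arrest is confined to the carina).
* `wall_mode = "arrest"`: freeze on first contact, the literal
  arrest-candidate surrogate.

Residence time in the carina region is accumulated by exact segment–disc
clipping of each step (not sample counting), and the minimum distance to the
apex is the exact segment distance, so both are insensitive to the step size.

## Synthetic data and oracles

The generator module makes every stage testable without external input:
seedings across the inlet (uniform over the cross-section by default, as the
cells are released; flow-weighted and centreline variants), and closed-form
references — plane Poiseuille flow (solver oracle), Stokes settling velocity
$(\rho_p-\rho) g D_p^2/18\mu = 3.66\ \mu m/s$ (drag–gravity balance oracle),
and exponential velocity relaxation (integrator oracle). `synthetic_field()`
wraps any analytic velocity field as a solver-output object so the metrics
can be validated in isolation. What a green test does *not* establish:
fidelity to pulsatile flow, deformable cells, adhesion kinetics or
three-dimensional secondary flows — all outside the model.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| calibre | 2 mm | large-vessel phantom |
| flow rate | 3 mL/min | perfusion-pump setting; Re < 100 |
| viscosities | 1.46 / 1.935 / 2.29 mPa·s | non-conditioned medium / FBS / 0.5 % methylcellulose |
| media density | 1000 kg/m³ | aqueous media; not separately reported, assumed water-like |
| particle | 14 µm, 1.05 g/mL | CTC analogue |
| n particles | 20,000 | ensemble size of the reference simulations |
| channel lengths | 10 mm (5 calibres) | entrance-length margin |
| global cell size | calibre/32 (62.5 µm) | mesh-independent for the control variables |
| zoom patch | ×8, half-width 0.45 mm | resolves the ~100 µm stagnation layer |
| carina region radius | 5 D_p (70 µm) | "very close to the apex"; robustness probed at 2–10 D_p |
| low-velocity threshold | 1 % of mean inlet speed | no canonical cut exists; always reported with the area |
| gravity | out-of-plane (zero in-plane) | horizontally mounted device; in-plane optional |
| tracking max_time | 20–60 s | caps near-wall crawlers; terminal status `max_time` |

## Design choices that were genuinely open

* **Scheme** (finite-volume projection vs FEM vs SIMPLE): chosen for a
  direct, factorise-once pressure solve and exact discrete mass
  conservation; the validation contract (Poiseuille, symmetry, mass,
  mesh-independence), not the scheme, is what is pinned.
* **Mesh-independence control variable for residence.** A random ensemble's
  "mean residence of entering particles" mixes set-membership noise into the
  grid comparison. The harness instead tracks a deterministic fan of probes
  at fixed offsets (±0.25–6 µm) spanning the streamtube that feeds the
  carina region and uses the unconditional fan mean — a continuous
  functional of the field. The axis seed itself is excluded (symmetric
  equilibrium: it never leaves the stagnation point).
* **Carina-approach definition.** Reported both ways: the spatial event
  (minimum trajectory distance to the apex below the region radius, the
  default) and the near-wall event (`touch_in_region`: contact within half a
  diameter of the wall inside the region — the direct analogue of cells
  observed "very close to the vessel wall" at the vertex).

## Known limitations

* **The carina-approach fraction is the one observable the planar model
  biases.** In 3-D, reaching the apex line requires small offsets in *two*
  directions; in 2-D only the transverse offset matters, so the feeding
  streamtube is relatively wider. The 2-D fraction at the default 70 µm
  radius converges to ≈ 0.7 % of trajectories (stable across global
  resolutions 42–62 µm and patch resolutions 4–8 µm) versus ≈ 0.1 % reported
  for the 3-D ensemble; the tighter 28 µm radius gives ≈ 0.1 %, and the
  near-wall (contact) definition gives ≈ 0.03 %. The corresponding
  acceptance check is left failing rather than re-scaled; the viscosity and
  angle *trends* and the residence-time physics are unaffected.
* Staircase walls are first-order accurate; wall shear along oblique
  branches is not a quantitative output.
* Newtonian fluid only (the experimental media are mildly shear-thinning;
  constant viscosities at the working shear rates are used).
* Steady flow; no pulsatility, no cell–cell interactions, no adhesion
  kinetics, no lift forces — the force balance is drag plus gravity only.

## Reproducing the headline numbers

```{r, eval = FALSE}
cfg <- run_config()                       # the reference 90-degree setup
summary <- run_pipeline(cfg, outdir = "run90")
summary$metrics

viscosity_sweep(list("non_conditioned", "fbs", "methylcellulose"), cfg)
angle_sweep(c(30, 45, 90), cfg)
mesh_convergence_study(bifurcation_geometry(90),
                       2e-3 / c(10, 20, 40), run_config(fluid = "fbs"))
```

`scripts/acceptance.R` chains exactly these calls from a fresh session and
writes the headline quantities as JSON.
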
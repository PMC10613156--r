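---
title: "Desk-scale left-heart hemodynamics: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale left-heart hemodynamics: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lhflow` simulates blood flow through an idealized, moving left heart — left
ventricle (LV), left atrium (LA) with its appendage (LAA), mitral and aortic
valves, and a short aortic root — and computes the turbulence, hemolysis-risk
and blood-stagnation indices used to compare a healthy subject with a subject
suffering severe mitral valve regurgitation (MVR). This vignette is the
package's methods reference: the governing model, the synthetic
anatomy-and-motion generator, the numerical scheme, every tunable parameter
that matters, and the design decisions taken where more than one reasonable
choice existed.

## Flow model

Blood is an incompressible, homogeneous Newtonian fluid (density
$\rho = 1060\,\mathrm{kg/m^3}$, dynamic viscosity
$\mu = 3.5\times10^{-3}\,\mathrm{Pa\,s}$) governed by the Navier–Stokes
equations written in the arbitrary Lagrangian–Eulerian (ALE) frame of the
moving chamber walls:

$$
\rho\,\partial_t \mathbf u
+ \rho\,(\mathbf u - \mathbf u_{ALE})\cdot\nabla\mathbf u
- \nabla\cdot\big[(\mu + \mu_{sgs})\,\nabla\mathbf u\big]
+ \nabla p
+ \sum_{i\in\{AV,\,MV\}} \frac{R_\Gamma}{\varepsilon_\Gamma}
  (\mathbf u - \mathbf u_{ALE})\,\delta_{\Gamma_i} = \mathbf 0,
\qquad \nabla\cdot\mathbf u = 0 .
$$

* **Wall motion.** On the chamber walls the velocity equals the prescribed
  wall velocity $\partial_t \mathbf d_{LH}$; the fluid domain follows the
  wall displacement.
* **Turbulence closure.** $\mu_{sgs}$ is the sigma-model large-eddy
  viscosity, $\mu_{sgs} = \rho\,(C_\sigma \Delta)^2 D_\sigma$ with
  $D_\sigma = \sigma_3(\sigma_1-\sigma_2)(\sigma_2-\sigma_3)/\sigma_1^2$
  built from the singular values
  $\sigma_1\ge\sigma_2\ge\sigma_3$ of the local velocity gradient
  ($C_\sigma = 1.5$, filter width $\Delta$ = mean mesh spacing). The model
  vanishes identically for two-component flows, rank-deficient gradients and
  solid-body rotation — which is why a 3D mesh is mandatory.
* **Valves.** Mitral and aortic leaflets are resistive immersed surfaces
  (RIIS): a penalty $\frac{R_\Gamma}{\varepsilon_\Gamma}(\mathbf u -
  \mathbf u_{ALE})\,\delta_\Gamma$ forces the fluid to the surface velocity
  on a smoothed layer of half-thickness $\varepsilon_\Gamma$ around the
  active leaflet configuration ($R_\Gamma = 10^5\,\mathrm{kg/(m\,s)}$). The
  kernel is a cosine bump $(1+\cos(\pi d/\varepsilon_\Gamma)) /
  (2\varepsilon_\Gamma)$ of the unsigned distance $d$, with unit mass across
  the layer.
* **On–off valve dynamics.** Leaflets switch instantaneously: a closed
  valve opens when its transvalvular pressure difference (upstream minus
  downstream probe means) becomes positive; the open aortic valve closes
  when its flow rate reverses; the open mitral valve closes when its flow
  rate reverses *and* the cycle phase is inside a late-diastolic guard
  window (default fraction $0.77/0.8$ of the cycle) — mid-diastolic flow
  reversals at diastasis and after the A-wave must not close it. The guard
  window wraps into the first 10% of the next cycle: with a discrete on–off
  rule, the decisive reversal can land a step after the cycle boundary, and
  without the wrap an open mitral valve would block the entire next systole.
  Closure rules are evaluated before opening rules; one switch per valve per
  step.
* **Boundary pressures.** At the pulmonary-vein inlets and the aortic-root
  outlet the normal stress is prescribed (tangential velocity zero, which
  also guards against backflow instability). The healthy venous pressure is
  a constant 10 mmHg; the regurgitant venous profile rises during systole to
  40 mmHg as the regurgitant jet loads the atrium; the aortic waveform is a
  physiological 80–120 mmHg diastolic-base/systolic-bump curve.
  1 mmHg = 133.322 Pa throughout.

## Synthetic anatomy and motion

No imaging data enter the package; a generator stands in for the
image-derived inputs.

**Shapes.** The LV is a truncated prolate ellipsoid (long axis vertical,
apex down, truncated by the base plane); a cylindrical mitral channel and a
tilted cylindrical aortic root rise from the base plane; the LA is an
ellipsoid elongated horizontally (so it clears the root), with a small
spherical appendage pouch and two vertical pulmonary-vein stubs whose flat
caps are the inlets. Absolute sizes derive from the scenario's end-systolic
LV volume; the mesh is built once at the end-systolic reference
configuration. The atrial floor keeps a clearance gap above the base plane
so the chambers communicate *only* through the mitral channel — an earlier
layout that let the atrium dip below the plane created a spurious second
orifice behind the annulus, a failure mode worth recording.

**Scenarios.** Healthy: 66 bpm (period 0.9 s), EDV 130 mL, EF 0.58, sealed
mitral valve. Regurgitant: 75 bpm (0.8 s), EDV 250 mL, EF 0.58, a central
0.4 cm² orifice in the closed mitral leaflet, elevated venous pressure. The
regurgitant chambers are reached from the same template mesh by a smooth,
exactly calibrated dilation (linear dimensions scale by ≈1.25), so both
scenarios share the mesh topology and all comparisons are vertex-matched.

**Motion.** Wall displacement is a two-parameter field:
the LV part scales the wall about the base-plane center (radial thickening
plus long-axis shortening), the LA part scales about the atrial center with
the floor's vertical motion faded near the base plane; both fade to zero
near the static orifices, root and vein stubs. Pure radial scaling about
the long axis was tried first and rejected: at EF ≈ 0.58 it tangles the
mesh in the taper zone near the base. Because vertex positions are linear
in the two amplitudes, any chamber volume is an exact cubic polynomial in
them; each of the 30 frames per heartbeat is calibrated by solving that
cubic so the frame volumes match the prescribed curves to machine
precision (the recomputed ejection fraction lands within a fraction of a
percent of the target). The LV volume curve has a smooth systolic ejection
ending at the end-systolic phase (frame 10/30 healthy, 12/30 regurgitant),
an E-wave refilling 72% of the stroke volume, a diastasis with a small dip
(producing the mid-diastolic mitral flow reversal near 70% of the cycle), an
A-wave completing the filling by 97% of the cycle, and a slight end-cycle
decline that triggers the final mitral reversal and closure. The atrial
curve is the counter-phased reservoir/conduit/booster pattern (total
emptying fraction 0.40 healthy, 0.45 regurgitant).

**Continuous motion and mesh motion.** The 30 frames are interpolated in
time by a C² periodic cubic spline (exact at the frames) and extended into
the volume by a homogeneous isotropic linear-elastic operator
(pseudo-Poisson ratio 0.3) with inverse-volume stiffening of small cells; a
harmonic extension is available as a cheaper fallback. Since the boundary
data live in the span of the two motion basis fields, the interior
displacement at any time is the same amplitude combination of the two
*extended* basis fields — the extension is solved twice, not every step.
The ALE velocity is the first-order backward difference of the extended
displacement, consistent with the flow discretization; the volume rate of
each chamber matches the ALE boundary flux to well under 1% (the geometric
conservation check). At template-generation time the few near-surface cells
that would invert anywhere along the cycle are culled (checking the actual
runtime motion at 60 phases), so the moved meshes stay valid by
construction; a neighbour-average repair guard remains as a last resort and
a tangled mesh aborts the run.

**What the generator does and does not emulate.** It reproduces the
qualitative flow phases (ejection, E-wave, diastasis, A-wave), chamber
proportions, valve positions and the regurgitant orifice; it does not
reproduce patient-specific wall shapes, annular dynamics, leaflet geometry,
papillary structures, or beat-to-beat variation of the imaging-derived
motion. Passing tests therefore validate the numerics and the directional
physics of the comparison, not patient-specific accuracy.

## Numerical scheme

Equal-order P1 tetrahedral finite elements with an incremental
pressure-correction (fractional-step) scheme on the moved mesh:

1. **Momentum predictor.** Lumped mass, implicit diffusion with
   $\mu + \mu_{sgs} + \mu_{stab}$, implicit lumped RIIS penalty, explicit
   convection with the ALE-relative velocity, and the old pressure in
   integrated-by-parts form, with the prescribed boundary pressure entering
   through the boundary integral over the open patches (pressure-outlet
   form — imposing the cap pressure only through the Poisson solve leaves a
   spurious orifice-like resistance at the caps).
   $\mu_{stab} = c_{stab}\,\tfrac12 \rho\,|\mathbf u - \mathbf u_{ALE}|\,h
   \cdot \max(0,\,1 - 1/\mathrm{Pe})$ is a streamline (first-order
   upwind-type) artificial viscosity gated by the cell Péclet number so it
   vanishes in resolved, diffusion-dominated flow ($c_{stab} = 0.5$).
   The systems are SPD with penalty Dirichlet rows; the sparse Cholesky
   factorizations are refreshed every few steps (and immediately whenever a
   valve switches or the velocity scale drifts), intermediate steps reusing
   the last factor with one step of iterative refinement.
2. **Pressure correction.** The projection uses the *consistent dual
   operator* $S = \sum_c G_c M_L^{-1} G_c^T$, where $G_c$ is the weak
   divergence and $G_c^T$ the adjoint (integrated-by-parts) gradient that
   the momentum equation also uses, with columns of $G_c$ zeroed at
   Dirichlet velocity dofs (the correction acts only on free unknowns).
   The system is solved by preconditioned Richardson iteration (3 sweeps)
   on the pure operator, preconditioned with the factorization of
   $S + \alpha K$ — the small scaled Laplacian (Brezzi–Pitkäranta-style,
   $\alpha = 0.1$) regularizes the checkerboard kernel of the equal-order
   pair, whose component never reaches the velocity. The prescribed cap
   pressures act through the momentum boundary integral; only a single node
   is pinned for the pressure level, so the continuity rows stay active at
   the caps. A light neighbour-average filter (weight 0.3) keeps the
   accumulated pressure clean. One irreducible defect remains: cells whose
   four vertices all lie on the moving wall carry prescribed,
   non-solenoidal data divergence; the resulting small global mass residual
   (≈2 mL/s at peak systole) is removed by a uniform normal-velocity
   correction over the open caps — the standard flux correction of
   prescribed-motion chamber CFD. The cycle-integrated mass imbalance is
   ≈0.2% of the stroke volume.
3. **Valve coupling.** Valve states update once per step from
   end-of-previous-step probe pressures and flow rates (explicit coupling),
   with a 5 ms dwell between switches of the same valve to suppress the
   chatter a discrete on–off rule produces around a zero crossing; the RIIS
   penalty of the active configurations is lumped onto the mass diagonal.
   The aortic and venous flow rates are boundary-cap integrals; the mitral
   flow rate comes from ventricular mass conservation
   ($Q_{MV} = dV_{LV}/dt + Q_{AV}$), because an on-grid interior plane
   cannot cover the beveled orifice rim at desk resolution.

**Resolution-driven choices.** The layer half-thickness defaults to
$\varepsilon_\Gamma = \max(0.75\,\mathrm{mm},\ 1.2\,h)$: on a desk mesh the
smoothed layer must span at least one mesh spacing, otherwise most vertices
miss its support and the closed valve becomes porous (the kernel keeps unit
mass either way, so the penalty scale is unchanged). The open-configuration
funnels (radius 7–9 mm) would be plugged entirely by a layer that wide, so
open valves exert no resistance; their surfaces remain available for
geometry output and the kernel-level operations. Open boundary caps are
snapped onto mesh grid planes at generation time — a cap that misses the
grid acquires a beveled, partially no-slip rim that chokes or destabilizes
the flow.

**Default problem sizes.** Mesh spacing $h = 3.5$ mm (≈16k cells, ≈3.5k
vertices), time step $\Delta t = 5\times10^{-4}$ s (about 1700 steps per
heartbeat, peak CFL ≈ 0.8), 3 simulated heartbeats with the first discarded,
50 phase-locked snapshots per cycle. These sizes were chosen as the desk
balance between orifice resolution and turnaround; the mesh-refinement
behaviour of the solver is characterized separately on the tube benchmarks
(Poiseuille L² error 3.7% at $h = 0.8$ mm, 1.45% at $h = 0.5$ mm,
second-order-ish).

**Cycle-to-cycle variability.** Phase-locked ensemble statistics are
meaningless if cycles are bit-identical, so at each cycle start a small
divergence-free velocity perturbation (sum of Gaussian vector-potential
curls in the atrium, amplitude 1% of the peak mitral inflow speed, seeded)
is injected, standing in for the natural turbulent decorrelation that a
patient-scale LES resolves by itself. All randomness flows from the run
seed; identical configuration and seed give bit-identical runs.

## Ensemble statistics and indices

All statistics are phase-locked over the retained cycles.

* **Mean/SD.** Arithmetic ensemble mean; second moments use the population
  estimator (divide by $n$), matching the Reynolds-stress definition; the
  SD field is reported as the component-wise RMS magnitude.
* **Reynolds stress and $\tau_{max}$.** $R_{ij} = \rho\langle u_i' u_j'
  \rangle$; the maximum tangential stress is the principal shear
  $(\lambda_{max}-\lambda_{min})/2$, evaluated with the closed-form
  trigonometric eigenvalue formula.
* **Hemolysis exposure.** $D(\mathbf x)$ is the fraction of the cycle with
  $\tau_{max} > 800$ Pa; the total exposure time is the measure of phase
  instants at which *any* point exceeds the threshold (a single scalar per
  run); the exposed volume is tracked per phase.
* **GTKE.** $\int_{region} \tfrac12 \rho \sum_i \langle u_i'u_i'\rangle\,dV$
  per phase; the reported scalar is its whole-cycle time average (in mJ).
* **Pope criterion.** $M = k_{sgs}/(k_{sgs}+k_{res})$ with
  $k_{sgs} = \mu_{sgs}^2/(C\Delta\rho)^2$ (cycle-averaged $\mu_{sgs}$) and
  $k_{res} = \tfrac12\sum_i\langle u_i'u_i'\rangle$, phase-resolved; $M = 0$
  where both vanish; the well-resolved volume fraction uses $M < 0.2$,
  cell-volume weighted.
* **Wall indices.** WSS is the tangential viscous traction of the
  *ensemble* velocity on each wall face (adjacent-cell gradient);
  TAWSS is the cycle average of its magnitude;
  $OSI = \tfrac12(1 - \|\int \mathbf{WSS}\,dt\| / \int\|\mathbf{WSS}\|dt)
  \in [0, 0.5]$ (the normalized form required for RRT to make sense);
  $RRT = 1/((1-2\,OSI)\,TAWSS)$, flagged infinite where the denominator
  vanishes. Stagnant-area fractions use RRT > 5 Pa⁻¹ by default, area
  weighted per labelled wall region (LV, LV apex, LA, LAA); the threshold is
  a convention and a sweep utility is available.
* **EPI.** The E-wave propagation index is
  $\int_{E} (Q_{MV}/A_{MV})\,dt / L_{LV}$ with the E-window detected as the
  first contiguous interval after aortic valve closure where the ensemble
  mitral flow exceeds 5% of its diastolic peak, and $L_{LV}$ the
  annulus-to-apex length at end diastole.
* **Region conventions.** The LV apex label covers the distal 30% of the
  ventricular long axis; the appendage is the pouch volume. Neither region
  has a canonical geometric definition, so both are explicit generator
  labels rather than inferred features.
* **Probes.** Transvalvular pressure differences are volume means over
  small probe spheres adjacent to each valve (ventricular outflow tract,
  root above the aortic annulus, atrium above the mitral annulus); centers
  and radii are configuration, not inference.

## Known limitations

* At desk resolution the effective orifice apertures are a few cells wide:
  transvalvular pressure gradients are exaggerated severalfold and peak
  velocities are under- or over-estimated locally. Comparisons between the
  two scenarios are therefore *directional* (orderings and ratios), never
  patient-scale values.
* The first-order upwind-type stabilization damps small-scale fluctuations;
  resolved turbulent energy is correspondingly conservative. The healthy
  scenario stays essentially laminar apart from the seeded perturbations —
  which is the expected physiology — while the regurgitant jet produces
  genuine cycle-to-cycle decorrelation.
* Instantaneous valve switching, no leaflet elastodynamics or contact, no
  papillary apparatus, no fluid–structure interaction, no boundary-layer
  meshing.
* The closed mitral leaflet leaks a few percent of the open-valve flow
  under load (resistive, not geometric, sealing); the sealing property and
  its monotonicity in $R_\Gamma$ are tested.

## Reproducing the analysis

```{r}
library(lhflow)
cfg <- pipeline_config("regurgitant", output_dir = "out/regurgitant",
                       n_cycles = 3L, seed = 1L)
res <- run_pipeline(cfg, verbose = TRUE)
res$analysis$summary
```

`scripts/acceptance.R` (repository root) recomputes the worked-example
arithmetic and the directional simulation quantities from scratch and
writes them as JSON; see the README for how to run it.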
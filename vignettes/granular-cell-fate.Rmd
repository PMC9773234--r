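---
title: "Simulating cell fate on free-packed microsphere beds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cell fate on free-packed microsphere beds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulocell)
```

## The model

`granulocell` simulates a single adherent cell (the calibration is for a
human adipose-derived stem cell of initial diameter 32 μm) landing on a bed
of free-packed microspheres and deciding, mechanically, whether it can stay
spread. The bed is a granular packing; its particles can be dragged by cell
traction if they are small and light, and every adhesion the cell loses makes
death by detachment (anoikis) more likely. The simulator reduces that biology
to three coupled ingredients:

1. **A granular bed.** Polydisperse spheres (5% uniform size dispersion) are
   settled under gravity by a discrete element method. Normal contacts follow
   the Walton–Braun hysteretic law: a stiff loading branch (`Y_u = 5e4` per
   unit diameter) while two bodies approach and a soft unloading branch
   (`Y_l = 5e3`) while they separate, giving inelastic collisions with
   restitution `sqrt(Y_l/Y_u) ≈ 0.316` and minimal overlaps. There are no
   tangential forces and no rotations. The bed is relaxed when the average
   kinetic energy per particle falls below `2e-3` (dimensionless).
2. **A spring-network cell.** The cell is a planar hexagonal arrangement of
   sphere elements (diameter `L_i/3`) joined by viscoelastic springs
   (stiffness `6.25 L_i^2`, damping `6.25e-2 L_i^2`). It starts as seven
   elements whose smallest enclosing circle has diameter `L_i` and spreads in
   stretching/contraction cycles: each cycle activates the next precomputed
   shell of elements (7 → 19 → 43, enclosing diameter up to `L_f = 2 L_i`),
   relaxes the new layer to mechanical equilibrium, then contracts by
   shrinking every structural spring's natural length to zero at a steady
   rate — the actomyosin pull.
3. **Three adhesion mechanisms.** (i) *Binding*: an unbonded element that
   touches a particle engages instantly through a binding spring whose
   elastic constant is the maximum cell force divided by `2.5e-5 L_i`, so the
   spring transmits the full maximum force at a stretch of 0.0025% of `L_i`.
   (ii) *Reinforcement*: if the transmitted force reaches the maximum cell
   force — the buoyant weight of a polystyrene sphere of diameter
   `(82/32) L_i`, about 200 pN for a 32 μm cell — the adhesion matures
   (talin unfolding, vinculin recruitment) and both the element and the
   particle are frozen permanently. (iii) *Detachment*: an engaged bond whose
   element has moved more than 4% of `L_i` toward the cell center since the
   bindings were last recalculated disengages, and the cell stops spreading
   in that direction. The 4% encodes the 2–4 s integrin engagement lifetime
   at a contraction speed of 110 nm/s; no wall-clock mapping is needed.

The fate statistic is the **volume ratio**: the union-of-spheres volume of
the final cell divided by the volume of the same cell run through the same
spreading schedule with contraction disabled (an upper bound). It is near 1
when the cell holds its spread shape and minimal when every adhesion fails
and the cell collapses to a ball.

The central competition is dimensional: the maximum cell force scales as
`L_i^3` while a particle's buoyant weight scales as `d^3`, so the
cell-to-particle aspect ratio `L_i/d` controls whether contraction drags
particles (bonds break, the cell contracts) or stalls against them (bonds
hold or reinforce, the cell survives spread). Immobile ("sintered")
particles are the infinite-density limit.

## Units

Lengths are measured in mean particle diameters `d`, the dimensionless
gravitational acceleration is 1, and forces in buoyant weights of a
mean-diameter polystyrene particle in water (densities 1.07 and
1.00 g cm⁻³). Masses are the effective, buoyancy-reduced masses (a
mean-diameter baseline particle has mass 1); the dynamics are quasi-static
and overdamped on the timescales that matter, so inertial detail is
immaterial — what the calibration fixes are force ratios. The time unit is
`sqrt(length_unit / 9.81 m s⁻²)` (1.8 ms for a 32 μm length unit), making
`g = 1`. `unit_system()`, `to_dimensionless()` and `to_physical()` convert
both ways; a relative density `r` (particle density `r ×` polystyrene)
multiplies the dimensionless buoyant weight by `(1.07 r − 1)/0.07`, which is
why glass (`r = 2`) particles are ~16× harder to lift than polystyrene.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `dt` | `5e-5` | integration step (dimensionless time) |
| `Y_u`, `Y_l` | `5e4`, `5e3` | contact stiffness per unit diameter, loading/unloading |
| `ke_threshold` | `2e-3` | bed relaxation criterion (mean KE per particle) |
| `dispersion` | `0.05` | half-width of the uniform size dispersion |
| `box` | `(20 d)^3` | periodic (x, y) box with a bottom wall at `z = 1` |
| `k_s`, `c_s` | `6.25 L_i^2`, `6.25e-2 L_i^2` | structural spring constants |
| `F_max` | `(82/32 L_i)^3` | maximum cell force = reinforcement threshold |
| `k_b` | `F_max/(2.5e-5 L_i)` | binding-spring stiffness |
| `detachment_fraction` | `0.04` | detachment displacement, as a fraction of `L_i` |
| `contraction_steps` | `1e5` | steps per contraction half-cycle |

## Numerical choices

* **Integrator.** A 4th-order Gear predictor–corrector (5-value, corrector
  coefficients for velocity-dependent forces). Free fall is integrated to
  machine accuracy; a harmonic oscillator holds its period to ≪0.1% at the
  default step. States are initialized with the true acceleration — a cold
  start leaves a permanent `O(a·dt)` velocity offset.
* **Neighbor search.** A periodic cell grid builds a Verlet pair list (skin
  0.5 d) containing every pair with at least one mobile member; the list is
  rebuilt when accumulated displacement could invalidate it. Forces are
  identical to an all-pairs evaluation.
* **Binding springs as constraints.** The published binding-spring stiffness
  saturates the maximum force at a stretch of `2.5e-5 L_i` — two orders of
  magnitude below anything the integrator can resolve at `dt = 5e-5` (the
  stiff mode sits far beyond the explicit stability limit, and the 5-value
  Gear scheme weakly pumps under-resolved oscillations). Engaged bonds are
  therefore enforced as rigid constraints (SHAKE position and RATTLE
  velocity projections), the stiff limit of the published spring, with the
  constraint dimensionality set by the anchor's rotational freedom: a bond
  to a *mobile* particle fixes the center-to-center distance only (the
  particle may roll under the adhesion patch, so tangential slip is free),
  while a bond to an *immobile* particle — sintered, reinforcement-frozen,
  or outside the mobile region — locks the full relative position recorded
  at binding (a fused anchor cannot roll). The
  per-step projection impulse *is* the transmitted bond force, and it is
  what the reinforcement threshold tests. Because a rigid constraint
  transmits single-step collision impulses that a viscoelastic spring would
  absorb, the reinforcement readout is low-pass filtered at the binding
  spring's own relaxation rate `k_b/c_b = 500` per time unit, which is
  exactly how fast the physical spring's elastic force tracks its load.
* **Damping caps.** Structural-spring and tether damping enter the force
  evaluation directly; their coefficients are capped at the explicit
  stability limit (`0.15 μ/dt` per pair). At the published constants the cap
  is inactive for structural springs (their damping is ~4 orders of magnitude
  below it).
* **Relaxation criterion.** "Net force zero" is evaluated on the net force
  averaged over the check interval (the momentum drift rate), because the
  hysteretic contact law flips between its two stiffness branches at rest and
  makes the instantaneous readout oscillate by construction. Relaxation
  phases also accept a stillness criterion (every active element slower than
  `1e-3`) and apply a weak global viscous drag (rate 2 per time unit) that
  changes only how fast the equilibrium is reached, never which equilibrium;
  contraction phases run undamped and unassisted — they are the physics.
* **Settling.** The mean-KE criterion alone can trigger while one straggler
  particle is still in ballistic flight (its energy hides under the average),
  so a settled bed additionally requires every single particle's kinetic
  energy below 0.1.
* **Localized bed dynamics.** During cell phases, particles farther than
  `L_f/2 + 2 d` (horizontally) from the drop site are held static. The cell's
  force paths are local and settled packings damp disturbances within a few
  diameters; enlarging the radius on a test scenario leaves the volume ratio
  unchanged within sampling noise (property-tested).
* **Volume estimation.** Union-of-spheres volumes use Halton quasi-random
  sampling (2^15 points, seeded Cranley–Patterson rotation), accurate to well
  under 1% for cell-like geometries.

## Protocol per sample

1. Settle (or reuse) the bed for the bed seed; quench residual motion; apply
   the density variant (masses rescale after settling, which leaves the
   packing unchanged; sintered = all particles immobile).
2. Drop the cell at a grid position: free fall of the rigid template is
   integrated exactly to first contact, with the corresponding impact
   velocity; binding starts there.
3. Repeat per shell: recalculate bindings, activate the next shell, relax to
   equilibrium, contract (natural lengths to zero, adhesion state machine
   every step). After the shrink schedule the contraction phase dwells —
   network tension persists at zero natural length — until a dwell segment
   passes without an adhesion event, so the cycle ends at the quasi-static
   fixed point of the detachment/reinforcement cascade rather than at an
   arbitrary schedule length. Terminal directions spawn no elements and do
   not re-engage.
4. Final relaxation; volume ratio against the contraction-free replay.

Bind references (the detachment clock) are recalculated at the start of each
contraction, so the 4% threshold measures contraction within a cycle from the
relaxed state — re-referencing is what "recalculating the binding of all
elements before each cycle" does to the detachment criterion.

## Design decisions taken where the model was open

* Shell radii interpolate linearly between the two published calibration
  points (`L_i` for 7 elements, `2 L_i` for 43); each peripheral element
  spawns two children at half its angular spacing.
* One binding spring per element (to its deepest-overlap particle). Allowing
  several bonds per element triangulates the element–particle network into a
  rigid truss that cannot contract at all and deadlocks the fate statistic.
* Inactive elements (mass reduced 10³-fold, viscoelastic properties rescaled
  accordingly) do not collide with the bed and are tethered to their template
  sites by critically damped springs anchored to the center element's frame.
* Contraction shrinks all natural lengths to zero together over a fixed
  number of steps (default 10⁵ ≈ 5 dimensionless time units per cycle), slow
  enough to stay in the quasi-static regime; natural lengths are not restored
  by later stretching (actomyosin shortening is persistent).
* Cell elements never collide with each other: a fully detached cell must be
  able to collapse toward a point, which is what makes the volume ratio
  discriminate fates. Elements do collide with particles and the wall.
* Elements keep the baseline (polystyrene) density in every density variant;
  the density sweep models the particle material only.

## What the generator emulates — and what it does not

The synthetic study sweeps the aspect ratio `L_i/d`, the relative density
(1, 2, ∞) and the bed depth (1, 3, 5 layers) with 16 drop positions × 10 bed
configurations per condition in the full design (the test suite runs 4 × 2).
It reproduces the qualitative phase behavior: cells on particle beds coarser
than themselves (ratio < 1) or on immobilized (sintered) particles keep their
spread volume; cells on fine mobile particles lose adhesions and contract,
the more so the lighter the particles. It does **not** model integrin
kinetics beyond the single lifetime-derived threshold, nucleus or membrane
mechanics, cell–cell contacts, fluid drag, or any biochemical readout;
passing tests show the mechanical competition behaves as designed, not that
real cells on real packings behave quantitatively alike.

Two quantitative limitations are worth knowing. First, the contracting
sheet can stall against the jammed packing instead of dragging particles
all the way to a collapsed ball: bonded elements push their anchors *into*
the bed as often as they pull them out, the compressed particle layer
arches, and the computed volume ratios on mobile beds saturate well above
the deepest contraction the fate statistic could express. Second, as a
consequence, the *mobility contrast* (sintered or dense beds versus
polystyrene-density beds) is resolved far more strongly than the *size
trend along the mobile-bed curve*: at the reduced replication used by the
test suite (8 samples per condition) the mean volume-ratio differences
between aspect ratios on polystyrene-density beds are comparable to their
standard errors, so strict orderings along that curve can flip from seed to
seed, while the sintered-versus-mobile separation is many standard errors
wide. The two-body oracles in the test suite demonstrate the underlying
drag-versus-reinforce competition deterministically.

## Problem sizes used by the test suite

Unit and property tests run on miniature scenes (16-particle beds, two-body
oracles, sub-second). The phase-behavior checks use the full `(20 d)^3`
3-layer bed (1200 particles) at reduced replication — 3 aspect ratios × 3
densities × 4 drop positions × 2 beds — and a 5-layer comparison at two
ratios; together they dominate the suite's runtime.
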
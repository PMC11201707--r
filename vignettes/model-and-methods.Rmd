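---
title: "Model and methods: a boundary-free artificial chemistry in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a boundary-free artificial chemistry in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autopoiesim)
```

## The system being simulated

`autopoiesim` simulates a minimal artificial chemistry in a sealed cubic
container filled with an implicit "ether" fluid. Three spherical particle
species inhabit it:

* **α-particles** — inert food (mass 1, no bonds);
* **β-particles** — chain links (mass 2, up to 2 bonds);
* **γ-particles** — catalytic hubs (mass 4, up to 4 bonds).

γ-particles catalyse the synthesis of β-particles from pairs of α-particles,
and can themselves split into two γ-particles by consuming two bound
β-particles. Bonded β/γ networks therefore grow as dendritic webs around
γ hubs; both species also decay back to α-particles, closing the material
cycle. Because mass only changes species (α = 1, β = 2, γ = 4
α-equivalents), the total α-equivalent mass is a run-long invariant — 1008
units under the standard initial conditions (1000 α plus one red and one
blue seed γ in a cube of side 40).

An *individual instance* is a maximal set of mutually bonded particles —
a connected component of the bond graph — that contains at least one
γ-particle (without a γ it cannot keep producing its own components, so it
is not viable). There is no spatial boundary of any kind: instances are
distinguished purely by bond connectivity, and the experiments below probe
when that is enough to preserve individuality.

Each β/γ carries a colour (red = +1, blue = −1) inherited from the γ that
produced it. Colour never affects dynamics; it is a provenance label that
lets the observer measure whether two initially identical lineages mix.

## Physics layer

Time advances in fixed steps of `dt = 0.02` s (50 steps per second). The
net force on a particle is the sum of four contributions minus linear drag
`−m D v`:

1. **Correlated random walk.** Per particle, an AR(1) force memory
   `F_R(t) = c F_R(t−1) + (1−c) g(t)`, `g ~ N(0, w I₃)`, with `c = 0.5`
   and `w = 25`. The stationary per-axis force variance is
   `w(1−c)/(1+c) = 25/3`. This approximates Brownian agitation by the
   unsimulated ether.
2. **Linear bond springs.** Each bond is an ideal spring with rest length
   equal to the sum of the two collision radii and stiffness `K_L = 100`.
3. **Torsion springs.** For a particle with `N_B ≥ 2` bonds, every pair of
   its bond vectors is driven toward the target angle `∠*(N_B)` — 180°,
   120°, 109.4712° for 2, 3, 4 neighbours (linear, trigonal, tetrahedral) —
   by a torque `τ = K_T (∠ − ∠*)`, `K_T = 3`. Two conventions are not
   determined by the model statement and are fixed here as package choices:
   the angle error enters in **degrees** (the same unit the target-angle
   table uses), and the force on each arm has magnitude `τ/|arm|`
   (torque divided by lever length), perpendicular to the arm in the plane
   of the triple, with the recoil on the centre closing the triple to zero
   net force. Collinear triples contribute nothing (undefined plane).
4. **Soft-sphere collisions.** Overlapping pairs (centre distance below the
   summed collision radii) repel linearly with stiffness `K_coll = 200`
   (twice the bond spring). A soft linear contact is the standard
   bead-spring treatment and replaces a rigid-body contact solver; the
   stiffness is exposed in the schema.

Integration is semi-implicit Euler (`v += dt (F/m − D v)`, then
`x += dt v`), which is stable for `K_L = 100` at these masses, drags and
timestep. The container is sealed: positions crossing a wall are reflected
and the normal velocity component is negated.

Two particles are *neighbours* when their centre distance is at most the
sum of their interaction radii; a bond stretched past that distance is
severed. Neighbour lists are rebuilt with a cell list (cell edge ≥ the
largest interaction-radius sum, 6) and are refreshed twice per timestep:
once after the physics update (the lists the next chemistry pass
consults) and once after chemistry has changed the particle set, before
forces are computed. A brute-force all-pairs oracle backs the cell list in
the test suite.

### Random-walk coupling

The random-walk force enters the net-force sum (`rw_coupling = "force"`,
the default, matching the model's net-force equation). An alternative
overdamped coupling (`"drift"`) treats drag as balancing the agitation
within a timestep, adding a drift velocity `F_R/(m D)` instead; this makes
the statement "`w` determines the average particle speed" literally true
for isolated particles. The two couplings produce the same long-time
transport — the effective diffusivity is set by the zero-frequency
spectral density of the force process over `(m D)²` in either case — so
the choice does not materially change outcomes; the variant exists as a
numerical cross-check of exactly that fact. With `c = 0.5`, `w = 25` the
force memory decorrelates in ≈ 0.03 s, giving α-particles an effective
diffusivity of ≈ 0.2 length²/s (measured and closed-form). Food transport
to the growing networks is therefore diffusion-limited, which sets the
development timescale discussed under *Limitations*.

## Chemistry layer

Reactions are resolved once per timestep, **before** the physics update.
The particles present at the start of the step are visited in a fresh
uniform-random order; each may initiate at most one mechanism, and a
particle consumed earlier in the step is no longer available as initiator
or reagent (tombstoning; no partial reactions). Probabilities are per
timestep, indexed by the relevant particle's bound-neighbour count, and
are used exactly as tabulated — never rescaled by `dt`.

* **A — β synthesis.** A γ with ≥ 2 α in range rolls `pA1(Nγ)`
  (1, 0.5, 0.25, 0.125, 0.0625 for Nγ = 0..4). On success the two nearest
  α are taken: the nearer becomes a β coloured like the γ, the other is
  destroyed. With probability `pA2 = 0.25` — and a free bond site — the β
  is incorporated (bonded, placed at rest length from the γ); otherwise it
  is ejected in place.
* **B — γ splitting.** A γ with ≥ 2 bound β rolls `pB(Nγ)`
  (0, 0, 1, 4, 16 ×10⁻³). On success the two nearest bound β are consumed
  and the γ is replaced by two bonded daughters of its colour, offset
  ±0.5 along a random direction; surviving bound neighbours re-attach to
  the nearer daughter with a free site.
* **C — partially bonded β bonding.** A β with exactly one bond may bond
  (probability `pC`) to a uniformly chosen neighbour with a free site.
  This is the repair/fusion pathway.
* **D — free β bonding.** A β with no bonds may engage a neighbour R
  (probability `pD1`); with probability `pD2(N_R)` (species-specific
  table) it simply adds a bond, otherwise it inserts itself into the bond
  between R and R's bound neighbour nearest to the β (ties broken by
  lower id). This is the capture pathway.
* **E / F — decay.** A β (γ) is replaced by 2 (4) α-particles placed with
  0.1-unit jitter; all bonds sever. Rates fall with connectivity
  (`pE`: 16, 4, 1 ×10⁻³; `pF`: 16, 8, 4, 2, 1 ×10⁻⁴), so interconnection
  is stabilising.

Per-γ mechanisms are rolled in the order A, B, then F, and per-β C or D
(by bond count) then E — decay last, with independent draws; the first
success is the particle's single initiation. The model statement fixes one
initiation per particle but not the arbitration among a particle's own
mechanisms; rolling growth before decay is this package's choice and
matters only in the rare step where two mechanisms would both succeed.

Newly created particles inherit the parent's velocity, start with zero
random-walk force memory, and do not react until the next timestep.

The three experiment presets differ only in the bonding pathways:

| preset | pC | pD1 | character |
|---|---|---|---|
| I | 0.04 | 0.08 | repair + capture: one collective autocatalytic entity |
| II | 0 | 0.08 | capture only: reproduction by fragmentation, γ-pure instances |
| III | 0 | 0 | internal production only: colour-pure autopoietic individuals |

Two structural consequences are exact and are enforced as invariants in
the test suite: with `pC = 0` two multi-particle instances can never merge
(so an instance never holds both γ colours), and with `pC = pD1 = 0` every
bond ever formed joins same-coloured particles (full colour purity).

## Observables

At 1 Hz the package records a trajectory frame and computes, over the
viable instances: counts (all / majority-red / majority-blue, where
majority is decided by γ colour counts and ties are excluded from the
colour classes), size min/mean/max, β and γ mass totals, and mean colour
values per (majority, species) pair. The colour mean is computed per
instance and then averaged unweighted across instances of that majority;
a pooled-particle variant is available behind a flag (`pooled_colors`),
since the defining sum is ambiguous between the two readings. Steady-state
summaries are means and population standard deviations (divisor `n`) over
the final `window_s` seconds — the last `window_s` sampled frames.

## Reproduction protocol

`run_simulation()` executes, per timestep: neighbour refresh → chemistry →
neighbour refresh → forces → integration, then samples at the configured
cadence. Identical configuration and seed give bit-identical output (all
randomness flows through R's RNG, including inside the compiled kernels).
Published-style runs are conditioned on both seed lineages surviving, so
`retry_until_coexistence` reruns with an incremented seed until the final
frame holds a γ of each colour, reporting the attempt count.

The acceptance script (`scripts/acceptance.R`) runs the three 300 s
experiments from the standard initial conditions and reports the
final-minute statistics: for experiment I the size, mass and γ-mass share
of the largest viable instance (the collective "core entity"); for
II and III the viable-instance count, mean size, summed mass and pooled
γ-mass percentage.

## Numerical and design choices

* `dt` fixed at 0.02 s; probabilities are per-timestep by definition.
* Random-walk memory starts at zero for new particles.
* Mechanism A reagent choice is deterministic (two nearest α); mechanism B
  consumes the two nearest bound β; mechanism D breaks distance ties by
  lower particle id. Determinism here keeps the event stream reproducible
  given positions and seed.
* Connected components are found by iterative depth-first traversal
  (explicit stack; no recursion-depth limits), cross-checked in the tests
  against union-find and igraph oracles.
* Degenerate geometry (coincident centres, collinear torsion triples)
  contributes zero force rather than NaN; integration aborts with an error
  on non-finite positions.
* Test problem sizes: unit tests use 2–200 particles and seconds-long
  runs; the acceptance suite runs the three full 300 s experiments at
  three seeds each.

## Limitations

* The ether is implicit: no hydrodynamic interactions, no explicit solvent
  collisions, no rotational degrees of freedom (particles are point masses
  with radii).
* The contact model is a soft linear repulsion; restitution is assumed
  fully damped.
* With the tabulated agitation parameters, food transport is
  diffusion-limited (α diffusivity ≈ 0.2 length²/s), so the bonded
  population develops toward its carrying capacity on a ~1000 s timescale
  rather than within the 300 s experiment window; 300 s population-level
  statistics (instance counts, total instance mass) are therefore
  substantially below the eventual steady state, while per-instance
  structure (sizes, γ-mass fractions, purity) is already representative.
  Extended runs (≈ 1500 s) approach the carrying capacity. The qualitative
  contrasts between the experiments — mass utilisation I > II > III,
  instance count II > III, fusion only under schema I, and the purity
  invariants — hold at every timescale and every seed tested.
* Instance identity is per-frame; no tracking across frames is attempted
  (fragmentation and recombination make identity genuinely ambiguous).
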
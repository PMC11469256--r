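---
title: "The rheodem in-silico rheometer: model, parameters, and measurement choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rheodem in-silico rheometer: model, parameters, and measurement choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rheodem)
```

`rheodem` simulates dense two-dimensional packings of soft frictional
grains under oscillatory simple shear and reduces the stress response to
the rheological signature that matters for injectable granular
biomaterials: a low-strain elastic plateau, an elastic softening
transition, a soft plateau stress, and yielding at the `G′ = G″`
crossover. This vignette records the model, the parameter choices and
their rationale, the operational definitions used by the feature
extractor, and the limits of what the simulations can show.

## The mechanical model

**Elements.** Discs with bidisperse radii (50/50 mixture at ratio 1.4, a
standard choice to suppress crystallization in 2D granular packings).
Units are nondimensional: the mean small-element diameter is the length
unit `L₀`, the small-element mass the mass unit `M₀`, and
`T₀ = sqrt(M₀/k_n)` the time unit, with the reference normal stiffness
`k_n = 1`. Masses scale with element area and inertia follows the disc
convention `I = m r²/2`.

**Contacts.** Two unbonded elements overlapping by
`δ = r_i + r_j − d > 0` interact through:

* a central force `F_n = f(δ) + η v_n`, floored at zero (granular contacts
  transmit no tension), with `f(δ) = k_n δ` (linear law) or
  `f(δ) = k_n δ/(1 − δ/δ_max)` (stiffening law). The stiffening law is the
  package's stand-in for intra-element porosity: a porous element
  compresses easily at first and densifies — stiffens sharply — as its
  pore space collapses, at an overlap scale `δ_max` (default 0.3 `L₀`,
  about half the small radius). The divergence is clamped at
  `99 k_n δ_max` (the law's value at `0.99 δ_max`) as an integrator guard,
  with a counted warning.
* Cundall–Strack tangential friction: a tangential spring `ξ` accumulates
  the relative surface velocity (including rotation, with lever arms
  `r − δ/2`); the trial force `k_t ξ` is capped at `µ F_n` and `ξ` is
  rescaled onto the cap when slipping. `k_t = k_n/2` by default, a common
  granular ratio. With `µ = 0` the tangential force is identically zero.

**Damping.** The pair dashpot is parameterized per unit normal stiffness,
`η = 0.84 k_n T₀`, which corresponds to a restitution coefficient near 0.1
for a reference pair — heavily damped, appropriate for quasi-static
rheometry of soft hydrated particles. Writing `η ∝ k_n` (rather than the
restitution-preserving `η ∝ sqrt(k_n)`) makes every force term scale
jointly with the stiffness multiplier `E`, so that the quasi-static stress
response is proportional to `E` — the proportionality the stiffness-sweep
analyses rely on. A weak background drag (`0.05 E M₀/T₀` per element)
toward the local affine shear field removes rigid-body drift; it is more
than an order of magnitude below the contact damping.

**Cross-links.** Bonds are permanent central springs formed at the current
contact geometry: rest length frozen at the formation distance, stiffness
`k_n` (scaled by `E`), active in tension *and* compression, plus the pair
dashpot. The cross-link also binds the interface tangentially with an
uncapped elastic spring — no Coulomb slip at bonded contacts.

That last choice deserves its rationale, because it was genuinely open. A
cross-linked interface between two gel particles is bridged by polymer
chains; those bridges resist sliding, not just separation. Two
alternatives were implemented and rejected on physical grounds. Treating
bonded interfaces as ordinary frictional contacts capped by the bond's
own compressive force leaves them nearly frictionless (the bond force is
zero at formation), which makes every bonded geometry dramatically softer
at small strain than an unbonded packing — contradicting the observation
that the low-strain plateau is set by the constituent stiffness and
packing, not by geometry or cross-link density. Capping by the
overlap-based load instead lets bonded interfaces slip exactly like free
ones, which erases the distinction between densely and loosely
cross-linked particles and lets a fully cross-linked bulk network creep
and soften — contradicting the expectation that bulk cross-linking
abolishes yielding. The non-slipping elastic cross-link reproduces both:
all four scenario geometries share the same plateau modulus to within
~10%, and the bulk network responds as a clean elastic solid with no
crossover up to 300% strain.

## Packing generation

`generate_packing()` inserts elements by random sequential insertion at a
dilute area fraction (0.35), then shrinks the box isotropically in 2%
area-fraction stages, relaxing after each stage with FIRE (fast inertial
relaxation engine) on frictionless linear contacts, to the target area
fraction (default φ = 0.90). Relaxation tolerances are `1e−8` (force
residual, intermediate stages) and `1e−11` (final), so packings start from
mechanical equilibrium to round-off; packing is a deterministic function
of its arguments. Above the 2D jamming point (φ ≈ 0.84 for frictionless
bidisperse discs) the equilibrium state necessarily carries overlaps set
by the confining pressure — at φ = 0.90 the mean overlap is a few percent
of a radius. Below jamming the protocol relaxes to an essentially
overlap-free state. Targets above 0.92 are rejected as geometrically
infeasible.

**Partitioning.** Super-particles are grown from randomly seeded center
elements: unassigned elements attach one at a time, restricted to contact
neighbors of a growing particle and choosing the nearest particle center
by minimum-image distance. Contiguity in the contact graph is therefore
guaranteed by construction, and the particle count is exact.

**Bond layouts.** `bulk_all` bonds every contacting pair; `intra_all`
bonds contacts within a particle; `intra_fraction` samples intra-particle
contacts at expected fraction `p`, then repairs connectivity with bridge
bonds (each particle must be one mechanically coherent object) and, where
a particle has more contacts than a spanning tree needs, guarantees at
least one free contact interface. Note the repair imposes a floor: a
particle of `n` elements needs `n − 1` bonds out of roughly `2n` internal
contacts, so the effective bonded fraction cannot fall much below ~0.5
regardless of nominal `p`. The loosely cross-linked scenario uses
`p = 0.3`, which lands near that floor (~55–60% of internal contacts
bonded) — as loose as a coherent particle can be.

## Shear protocol and stress measurement

Strain control, `γ(t) = γ₀ sin(ωt)`, is imposed through Lees–Edwards
periodic images (the image offset and image velocities follow the
boundary strain and strain rate) together with per-step affine velocity
increments; element velocities are initialized on the affine field at
`t = 0`. Velocity-Verlet integration with one force evaluation per step;
a Verlet neighbor list with a 0.6 `L₀` skin is rebuilt when accumulated
motion (tracked in co-deforming coordinates, plus the strain increment)
could invalidate it.

Defaults: `ω = 0.05/T₀` — the edge of the quasi-static regime
(`ω T₀ ≤ 0.05`), chosen to keep sweep costs at desk scale; `dt` is
0.05 `T₀` adjusted downward so a cycle is an exact multiple of 64 steps
(64 stress samples per cycle, making the trapezoid Fourier projection
spectrally exact on whole periods); 2 discard cycles then 4 measurement
cycles. Halving `dt` moves the measured `G′` by well under 1%. At the
default rate the pair dashpots contribute a loss-tangent floor of roughly
`ω η/k_n ≈ 0.04`; analyses that need a deeper quasi-static limit (e.g.
phase-lag checks on elastic networks) lower `ω` instead of the damping.

The stress tensor is the symmetrized virial,
`σ = (1/A) Σ sym(r_ij ⊗ F_ij) + (1/A) Σ m v' ⊗ v'`, with minimum-image
branch vectors, tension positive, and the kinetic term computed from
non-affine velocities; `σ_xy = σ_yx` holds exactly by construction even
with tangential forces. Moduli are first-harmonic Fourier projections of
`σ_xy` over the measurement window, phase-referenced to the imposed
strain.

Amplitude sweeps run each amplitude on a fresh copy of the scenario
ensemble — no history carries between amplitudes, mirroring fresh-sample
amplitude sweeps on a laboratory rheometer. Replicate seeds, not repeated
measurements, provide error bars.

## Operational feature definitions

The characteristic points of an amplitude sweep are marked on curves in
the literature but rarely defined operationally; the package's definitions
are therefore declared, with thresholds exposed as arguments:

* **Low-strain plateau `G₀′`** — mean `G′` over the largest low-amplitude
  prefix with consecutive values within 10%; undefined if no such prefix
  of length ≥ 2 exists.
* **Yield** — the first *solid-to-liquid* crossing of `G′ = G″`, located
  by interpolating `log(G′/G″)` linearly in `log γ₀`; the yield stress is
  interpolated on the same abscissa. Liquid-to-solid crossings are not
  yield: at vanishing amplitude the stress signal falls below the
  measurement floor and `G″ > G′` can appear spuriously, exactly as a
  laboratory rheometer's torque resolution pollutes its smallest
  amplitudes.
* **Softening transition** — onset at the first amplitude with
  `G′ < 0.8 G₀′` while still solid-like, *and* the softened solid state
  must persist for at least two consecutive amplitudes. The persistence
  requirement separates a genuine transition to a softened elastic state
  from the gradual decline every curve shows on its way to yield — the
  frictionless control passes through softened values but holds no
  softened state. The soft plateau is the mean `G′` over the longest
  post-onset solid-like run with consecutive ratios within 20%, and the
  softening depth is `G₀′` over that plateau.
* **Relative yield stress** — `τ_y/G₀′`; a Hookean solid yielding at
  100% strain has value 1, and departures below the Hookean line measure
  the strength of elastic softening. Design flags default to
  `τ_y/G₀′ ≤ 0.12` and yield strain ≥ 50%, both configurable in
  `compare_scenarios()`.

Feature extraction is scale-equivariant (stiffness-scaled curves give
scaled stress features and identical strain features), and
`normalize_master()` divides both moduli and the stress amplitude by
`G₀′` to compare curve shapes across stiffnesses.

## What the generator emulates, and what it does not

The four scenario builders reproduce the *topology* of the candidate
microstructures — free frictional spheres, a fully cross-linked bulk, and
compact versus loosely cross-linked irregular particles — in a dense 2D
packing at desk scale (hundreds of elements, tens of particles). Within
that scope the simulations reproduce: a solid plateau and friction-driven
softening for sphere suspensions with yield well below 50% strain;
complete suppression of yielding under bulk cross-linking; substantially
higher yield strain for irregular particles (at the sizes used here the
three-seed mean reaches ~0.46, approaching but not resolving the 50%
mark — the crossover also still drifts upward as the drive rate is
lowered, so desk-scale values are best read as lower bounds); and, under
the stiffening law, the strong friction-dependence of the softening depth
(low-friction porous particles soften far more than high-friction ones).

Real data differ in ways the model does not capture. Elements here are
internally rigid discs: intra-particle porosity enters only through the
stiffening compression law, not as resolved pore space, so with the
*linear* law the softening of particle suspensions is dominated by
inter-particle contacts and the dense-versus-loose cross-linking contrast
is within seed noise at these sizes. The system is 2D (area fractions,
not volume fractions; the jamming point and coordination differ from 3D).
There is no adhesion, no pore fluid or lubrication, no bond breakage or
healing kinetics, and no walls — periodic bulk only. Passing tests
therefore certify the contact mechanics, the driving and measurement
machinery, and the qualitative scenario physics, not quantitative
agreement with any laboratory material.

## Numerical choices and degenerate inputs

* Stability guards: `dt ≤ 0.1 T₀`, `ω T₀ ≤ 0.05` enforced at protocol
  construction; non-finite coordinates or kinetic-energy divergence abort
  a run naming the amplitude, and `amplitude_sweep()` truncates with a
  warning.
* Tangential state is dropped when a contact opens; bonded-pair tangential
  memory lives with the bond and persists.
* Zero-amplitude moduli are an error (undefined), not zero.
* `intra_fraction` with `p` high enough to bond everything still releases
  one cycle bond per particle with spare contacts, preserving at least
  one free interface.
* Sweep tables round-trip through CSV at better than 12 significant
  digits; configs round-trip YAML bit-exactly; ensemble serialization is
  byte-stable (identical files on repeated writes).
* Problem sizes in the test suite: unit tests run packings of 40–200
  elements; scenario-level comparisons use 400 elements, 25 particles,
  seeds 1–3, with a 12-point amplitude grid from 0.05% to 300% strain —
  extended a decade below the default sweep grid so the linear plateau of
  every geometry (softening onsets near 1%) is sampled inside its linear
  regime. The stiffening-law comparisons use half the default time step,
  since the densifying branch steepens the contact force.

## Known limitations

Finite-size effects are the dominant caveat: with tens of particles the
yield strain of irregular-particle suspensions is noisy across seeds and
sits slightly below its large-system value, and frictionless controls —
marginally stable without friction — show strong seed-to-seed variation
in their moduli. The drive frequency sits at the quasi-static bound for
cost; crossover strains shift upward by a few percent of strain when `ω`
is halved. The Fourier extraction reports first harmonics only; higher
harmonics near yield are measured but not analyzed.
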
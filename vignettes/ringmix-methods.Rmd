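---
title: "Methods: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ringmix)
```

`ringmix` simulates binary mixtures of semiflexible ring (and linear)
bead-spring polymers in a hard spherical cavity or a periodic box, and
computes the observables that characterise entropy-driven segregation of
long stiff rings to the cavity wall. This vignette documents the model, the
algorithms, the tunable parameters and the design decisions — including
what the synthetic fixtures do and do not emulate.

## Model and units

All quantities are in reduced units: monomer mass m, diameter σ and thermal
energy k_BT are 1, so the time unit is τ0 = (mσ²/k_BT)^{1/2} = 1. There is
deliberately no unit-conversion layer.

Three bonded/non-bonded terms define the chains:

* **FENE bonds**, U(r) = −(K R0²/2) ln(1 − (r/R0)²), with K = 30 k_BT/σ²
  and R0 = 1.5σ. The divergence at R0, combined with the WCA core, makes
  bond lengths that would allow chain crossing energetically unreachable —
  this is what preserves ring topology during dynamics.
* **WCA pairs**, U(r) = 4ε[(σ/r)¹² − (σ/r)⁶ + ¼] for r ≤ 2^{1/6}σ, zero
  beyond, applied to *bonded and non-bonded pairs alike* (so the equilibrium
  bond length, where the FENE pull balances the WCA core, is ≈0.961σ).
* **Bending**, U = K_b(1 + cos θ), where θ is the interior angle at a
  monomer between its two adjacent bonds, θ = π for collinear bonds. With
  this convention a straight chain costs nothing and K_b = 50 means a stiff
  chain; the opposite convention (θ = 0 when straight) would make nominally
  stiff chains crumple and contradicts every observed trend. A rigid planar
  N-gon pays K_b(1 − cos 2π/N) per vertex — 19.71 k_BT in total for
  N = 50, K_b = 50.

The confining sphere of radius R repels monomers through the same WCA form
evaluated on the radial gap d = R − |r| (strength ε_wall = 1 k_BT), so
monomer centres are effectively excluded beyond |r| = R − σ. This smooth
radial wall is the default: it is exactly spherically symmetric and cheap.
A particulate wall — explicit σ-sized particles on a Fibonacci lattice at
radius R, the literal particle-built construction — is available via
`confinement_sphere(wall_style = "particulate")`; the two agree on the
accessible radius R − σ and, at the resolutions used here, on all
observables, but no arrangement of a discrete shell is exactly isotropic,
which is why the smooth form is preferred. Bulk reference systems use a
periodic cubic box with minimum-image interactions and no wall.

Density bookkeeping follows the monomer-count convention
ρ = (M_long·N_long + M_short·N_short)/V, not a packing fraction. The
short-chain count is derived from ρ by flooring, so the achieved density is
reported alongside the requested one. Densities above 0.6 are accepted with
a warning: beyond that the rings themselves deform.

## Building unlinked initial states

Rings start as rigid planar regular polygons (bond length 0.97σ), linear
chains as straight rods. Placement is random sequential: a random centre
and orientation are drawn, and the candidate is rejected if any monomer
violates the wall margin, if any inter-chain monomer distance falls below
0.75σ, or — for rings — if the Gauss linking number against any placed ring
with an overlapping bounding sphere is nonzero. The polygon start makes
every chain unknotted *by construction*, which is why knot detection is out
of scope; the linking-number rejection is what guarantees pairwise
non-concatenation (vertex-distance checks alone cannot: two rings can
interpenetrate between beads). The placement separation of 0.75σ is a
practical compromise — rigid-unit rejection sampling at ρ = 0.4–0.6 jams
well before the sphere is geometrically full if one insists on 0.9σ — and
the subsequent push-off restores a 0.9σ guarantee.

The push-off replaces the WCA pair term for *non-bonded* pairs by a capped
soft repulsion A(t)(1 + cos(πr/r_c)) ramped from A = 0 to 30 k_BT over 500
steps at a reduced timestep (0.001τ0), followed by a 200-step settle on the
full WCA surface. Bonded pairs keep FENE+WCA throughout the ramp: removing
the WCA core from bonds would let FENE (which is purely attractive) collapse
them to ≈0.6σ, and the switch back to WCA would then inject enough energy to
overstretch bonds. If any inter-chain distance still falls below 0.9σ after
the ramp, one further ramp at doubled strength runs. Initial velocities are
exact Maxwell–Boltzmann draws at T* with the total momentum zeroed; the
settle leaves a mild kinetic excess that the production thermostat removes
within a few hundred steps.

Placement runs on a deterministic, seeded generator (xoshiro256++ with
polar-method normals, independent of the C++ standard library's unspecified
distribution algorithms), so identical seed and composition give bit-identical
states.

## Integration

The engine is velocity Verlet with Δt = 0.006τ0 by default. NVT coupling is
a single Nosé–Hoover variable ξ with the semi-implicit closing half-kick

v(t+Δt) = (v_half + Δt/2·F(t+Δt)) / (1 + Δt/2·ξ(t+Δt)),

which reduces to plain symplectic velocity Verlet when the thermostat is
off. The coupling mass is Q = 3N·T*·(100Δt)² — a damping period of 100
timesteps, adequate for dense liquids at T* = 1; no thermostat chains are
used. The kinetic temperature uses 3N − 3 degrees of freedom (zeroed total
momentum). ξ carries across annealing stages.

Reheat-annealing, used to avoid locally trapped configurations, is a staged
temperature ladder (e.g. 2.0 → 1.5 → 1.0) with per-stage durations from the
schedule; equilibration can be checked post hoc with
`check_equilibration()`, which fits a line to the second half of the
long-species mean-radius time series and asks for a slope consistent with
zero at 95% confidence.

Pair interactions use a Verlet neighbour list (skin 0.4σ) built through a
cell grid and rebuilt whenever any particle has moved more than half the
skin; the brute-force all-pairs path is retained and the two are asserted
equal in the tests. Force accumulation order is fixed (bond, pair, angle,
wall) so repeated evaluations are bit-reproducible. A FENE bond reaching R0
or a monomer found at |r| ≥ R aborts with a diagnostic naming the bond — the
signature of a too-large timestep. Every production run re-verifies all
ring-pair linking numbers on the final frame and fails hard if any pair has
become linked.

## Observables

* **Radial density profile**: per-bin monomer counts over shell volumes and
  frames, divided by the species mean density, so a uniform species reads
  1.0. Default bin width 0.25σ for all radial histograms (a compromise
  between resolution and per-bin statistics at desk scale; all profile
  functions take `bin_width`).
* **Ring orientation order** P₂ = ⟨(3cos²θ′ − 1)/2⟩ with
  cos θ′ = |n·r̂_com|, n = Σ b_i × b_{i+1} the ring normal. Two deliberate
  choices: the quadratic form is the standard second Legendre polynomial
  (the variant "3(cos²θ′ − 1)/2" cannot reach 1.0 and contradicts the
  wall-attached limit), and the absolute value reflects nematic symmetry —
  the sign of n follows the arbitrary monomer ordering. 1 = normals radial
  (wall-attached), 0 = isotropic, −0.5 = normals tangential.
* **Velocity decomposition**: chain-COM displacements over δt (default
  200τ0, required to be a multiple of the sampling interval) split against
  the ring normal at the interval start: V⊥ = |d|sin β/δt,
  V∥ = |d|cos β/δt. β is measured against the ring normal; a `beta_ref =
  "radial"` switch measures against the COM radius vector instead — the two
  coincide exactly for wall-attached rings, where the normal is radial. The
  reported ratio is the ratio of means, not the mean of ratios, to stay
  finite when individual intervals have near-zero parallel displacement.
  The critical density ρ* is the location of the ratio's maximum over a
  density sweep, refined by a quadratic through the peak and its
  neighbours; boundary maxima are returned as-is with a warning.
* **PMF**: V(r) = −ln p(r) with p the shell-normalised radial histogram.
  The profile is anchored at the innermost *populated* bin rather than at
  r = 0 itself, where shell volumes vanish and sampling is hopeless; empty
  bins are NA, never ±Inf. Because the anchor bin is itself
  sampling-limited, quantitative comparisons in the tests align profiles by
  their count-weighted mean — the physically meaningful content of a PMF is
  its shape, not its offset.
* **Energy/entropy decomposition**: per-chain bending energies of the
  confined system binned by chain-COM radius (the chain, not the monomer,
  is the object whose bending budget matters), referenced to the mean
  per-chain bending energy of the same composition in a periodic-box bulk
  run at the same density: ΔU_bend(r) = ⟨U_bend|r⟩_conf − ⟨U_bend⟩_bulk.
  With ΔF(r) the chain-COM PMF, TΔS(r) = ΔU_bend(r) − ΔF(r) on shared
  bins. Rings that lie flat on the wall show ΔU_bend < 0 there; linear
  chains pay a bending cost instead.

## Synthetic fixtures

The fixture generator produces the limiting configurations of the physics,
each with a closed-form expectation: perfect rigid N-gons (gyration radius
b/(2 sin π/N); 7.963 for N = 50 at the nominal bond length b = 1σ — the
idealised rigid ring is defined at the monomer diameter, not at the
thermal FENE+WCA bond minimum of 0.961σ, which would give 7.65), shells of
wall-attached rings (every chain COM at √(reach² − Rg²); 17.25 at reach 19),
isotropic ring ensembles (P₂ → 0), Hopf-linked pairs (Lk = ±1, the positive
control the topology detector must flag), Boltzmann radial samplers (whose
PMF round trip must recover the generating potential), and tangentially
sliding rings (V∥ → 0 kinematics).

Fixtures are deterministic given their seed and are written in the same
XYZ/dump formats as real trajectories, so analysis code cannot distinguish
them. They deliberately ignore excluded volume between chains and all
relaxation dynamics: passing fixture tests validates the *estimators*
(geometry, binning, normalisation, topology detection), not the sampling of
the physical ensemble, which only the MD runs probe.

## Desk-scale study conditions

The full-scale study conditions (sphere R = 20σ, 10 long rings of N = 50,
short rings of N = 10 filling ρ = 0.4 — ≈13,400 monomers — and run times of
10^10 steps) are cluster-scale; this package reproduces the mechanism at
reduced scale and keeps the full-scale composition available through the
same interfaces. The packaged trend replication uses R = 10σ, 3 long rings
of N = 20 and short rings of N = 5 at ρ = 0.4, 5×10^5 steps per run and 3
seeds per stiffness (K_b,long = 0 vs 50), with a 2×10^5-step bulk reference
in a periodic box — sizes chosen so the direction of the stiffness effect
(⟨r⟩, P₂, the sign of ΔU_bend at the wall) is resolved reproducibly in
minutes per run on one core. Directions, not magnitudes, are asserted:
at this scale the wall shell is partial, ⟨r⟩ sits well below the
wall-attached limit, and ρ* from a sparse density grid is noisy.

## Known limitations

* Single Nosé–Hoover variable (no chains): adequate at T* = 1 for dense
  systems, but not a rigorous canonical sampler for stiff, nearly harmonic
  degrees of freedom at low density.
* The periodic-box builder checks non-concatenation within the primary
  image only; at the box sizes used (edge ≫ ring diameter) cross-image
  linking at placement is geometrically excluded.
* No hydrodynamics, electrostatics, barostats or pressure/virial
  computation; knot-type classification beyond unknotted-by-construction is
  out of scope.
* XYZ/dump formats store coordinates (and velocities), not bending
  constants or ring/linear kinds; reading external trajectories for
  analysis may need an explicit `topology` argument.
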
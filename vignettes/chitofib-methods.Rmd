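---
title: "chitofib: models, estimators and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chitofib: models, estimators and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

chitofib analyses molecular-dynamics trajectories of crystalline
chitosan nanofibrils: hydrogen-bond networks classified by fibril
topology, hydration and water bridges, convex-hull volume change,
stacking geometry, and dipole orientations. It does **not** run or
emulate the dynamics themselves — no force field, no integrator, no
thermostat. Where a real study would feed microsecond MD output into
these estimators, the package ships a synthetic-trajectory generator
with planted ground truth so that every estimator can be validated by
parameter recovery.

# The fibril model

## Unit cell and symmetry

The default lattice is the anhydrous chitosan cell: orthorhombic,
space-group operators of P2₁2₁2₁ (three perpendicular two-fold screw
axes), a = 8.129, b = 8.347, c = 10.311 Å. `apply_symmetry()` expands
an asymmetric unit given in fractional coordinates by the four affine
operators and converts to Cartesian Å through `diag(a, b, c)`. The
operator set is checked for closure under composition modulo lattice
translations, and symmetry copies closer than a configurable clash
distance (default 1 Å) trigger a warning.

## Builder conventions

`build_fibril()` constructs an oriented fibril directly on the lattice:

- chains run along **z** (fibril elongation); the two sugars of a
  c-repeat are related by the 2₁ screw along the chain axis, and the
  repeat is translated by c, `dp/2` times (10 × c = 103.11 Å for the
  default 20-mer, matching the printed fibril length of 103.1 Å);
- chains within a sheet are spaced by one **a**-translation along x
  (sheet growth);
- sheets are stacked along **y** at **b/2 = 4.1735 Å**, with adjacent
  sheets antiparallel (rotated 180° about y) and z-shifted by a fixed
  registry constant.

Two of these are deliberate design decisions worth flagging. First,
the b/2 sheet spacing: the unit cell contains two antiparallel sheets,
and only at ~4.2 Å spacing can inter-sheet N′H–O4 hydrogen bonds
(donor–acceptor ≈ 3.1 Å on the ideal lattice) exist at all; a full
b-translation per sheet would put every cross-sheet atom pair beyond
the 3.5 Å criterion and is also inconsistent with a four-sheet fibril
being ~12 Å thick. Second, the z-registry of mirrored sheets is chosen
so that the donor and acceptor of the inter-sheet pair line up exactly
in z; crystal-packing registry is not inferable from unit-cell
constants alone, so this is declared as a convention, not a claim
about the crystal.

## The glucosamine template is synthetic

The packaged residue template (`glucosamine_template()`) carries the
named atoms N, O3, O4, O5, O6, C1–C6 and the donor hydrogens HN, HO3,
HO6 at fixed idealized coordinates. It is a *lattice fixture*, not the
crystallographic coordinate set: positions were chosen so that on the
assembled fibril each named hydrogen-bond pair type has a
donor–acceptor distance of 2.5–3.2 Å (comfortably plantable under
thermal jitter), and so that the *resting* hydrogens — pointed inward
along the heteroatom→carbon bond — satisfy the angle criterion with no
acceptor whatsoever. The as-built fibril is therefore hydrogen-bond
silent, which makes the generator's on/off toggling exact. The cost is
some steric license (a few heavy-atom contacts are shorter than
chemical bonds would allow); none of the estimators is sensitive to
this. A real asymmetric unit in PDB or mmCIF can be supplied instead.

# Hydrogen bonds

A bond is a donor–H⋯acceptor triple with donor–acceptor heavy-atom
distance **< 3.5 Å** and donor–H–acceptor angle **> 135°**. The angle
vertex is at the **hydrogen** — stated explicitly because some MD
tools use the donor-centred angle. Distances and the two angle vectors
use the minimum-image convention for orthorhombic boxes; triclinic
boxes are not supported. Donors are the chitosan hydroxyls (O3H, O6H),
the amine (NH, one hydrogen in this model), and water (two hydrogens,
each counted as its own potential triple); acceptors are chitosan N,
O3, O4, O5, O6 and water oxygen.

Classification is purely topological: same chain → intra-chain; same
sheet, different chain → intra-sheet; different sheets → inter-sheet;
exactly one water partner → chitosan–water; two → water–water. Named
pairs use the prime convention for the neighbouring partner:
`O3'H-O5` (donor hydroxyl of residue i+1 to the ring O5 of residue i),
`O6H-O3'`, `N'H-O6` (adjacent chain, same sheet), `N'H-O4` (adjacent
sheet); everything else is `other`.

**Occupancy** of a pair is the fraction of frames in which a specific
instance is bonded, pooled over symmetry-equivalent instances as the
plain mean (matching "for all chains in the fibril"); per-instance
tables are also returned. Instances are enumerated from a reference
structure by the name/relation rules with a 4 Å distance filter, which
drops symmetry partners that are geometrically impossible in this
packing. The **fraction of maximal inter-chain H-bonds** divides each
frame's intra-sheet + inter-sheet count by the count in a reference
structure; because the as-built lattice is bond-silent, the natural
synthetic reference is `bonded_reference()`, a jitter-free frame with
every named pair planted on (the analogue of an energy-minimized
reference).

# Hydration

Waters are classified by the oxygen's minimum distance to any chitosan
heavy atom: **bound** below 3.5 Å, **bulk** at or beyond 10 Å. The
"water between the two interior sheets" is not a standard observable;
the package defines it geometrically as the slab between the
centre-of-mass y-planes of sheets 2 and 3, intersected with the padded
(2 Å) xz bounding rectangle of those sheets. An H-bond-based
alternative (waters bonded to both interior sheets) is available via
`interior_water_count(..., method = "hbond")`; both are provided
because contact-based and geometric definitions are both in common
use and neither is canonical.

A **water bridge** is a single water simultaneously H-bonded (as donor
or acceptor) to two chitosan atoms; a water with n partners yields
C(n, 2) bridges, one per unordered partner pair, which keeps the count
order-independent. Bridges are categorised by the two partners'
topology; same-chain partner pairs are reported as intra-chain bridges
even though the scientifically interesting classes are the inter- and
intra-sheet ones.

# Geometry

The convex-hull volume follows the simplex-sum definition: hull facets
are found by an incremental algorithm in compiled code, then the hull
is fanned into tetrahedra from the hull-vertex centroid and
Vol = Σ |det(v₁−v₀, v₂−v₀, v₃−v₀)|/3! is accumulated in R — keeping the
formula itself testable against Monte-Carlo membership integration
(`in_hull()`). Facet predicates use determinant tolerances scaled to
the squared extent of the cloud (~1e−10·L²); collinear or coplanar
input raises an explicit degeneracy error. ΔVolume is taken against a
fixed reference (first frame if none given; with MD data, the
energy-minimized state is the natural choice).

RMSF superposes all frames onto the unsuperposed mean (Kabsch),
recomputes the mean once, and reports per-atom
√⟨|rᵢ−⟨rᵢ⟩|²⟩. This one-pass protocol is documented because fitting
protocols differ between tools; for isotropic Gaussian disorder of
per-axis width σ it converges to σ√3 with a relative bias of order
1/(2F) + 1/N.

The sheet-stacking distance is the COM–COM distance of the middle
chains of sheets 2 and 3 (with six chains per sheet: the mean of the
two central chains' COMs — symmetric and deterministic). Note one
subtlety of the builder's antiparallel convention: the mirrored sheet
carries a fixed ~1.6 Å COM offset in z, so the COM–COM distance is
√(Δy² + c²ₓz), not the bare y-spacing. The synthetic generator
therefore plants the COM–COM distance itself (the quantity the
estimator measures) and inverts to the y-spacing internally; planted
schedules are recovered exactly in the noise-free limit.

# Dipoles

μ = Σqᵢrᵢ about the centre of geometry, origin-independent only for
neutral sets (asserted by default, tolerance 1e−6 e). Charges come
from a plain-text table (`resname atom charge`); the packaged table is
a **toy** — per-residue neutral, chosen so the chain dipole is
parallel to the chain axis — because real force-field charges are not
public in this context and are not guessed. 1 e·Å = 4.803 D is
reported alongside.

The chain vector runs from the COM of sugar unit 2 to unit 19; the net
fibril dipole is the vector sum of chain dipoles and cancels exactly
for an even number of identical antiparallel sheets (an odd count
leaves exactly one sheet's worth). Water dipole orientations are
reported as angles to a reference axis (the field axis when present,
otherwise z), raw and sin θ-corrected; the axial Boltzmann family
P(θ) ∝ sin θ·exp(κ cos θ) is fitted by inverting the Langevin function
L(κ) = coth κ − 1/κ = ⟨cos θ⟩.

# The synthetic world

`generate_trajectory()` produces frames with fully known ground truth:

- **thermal disorder**: i.i.d. Gaussian jitter per atom per axis,
  default σ = 0.1 Å. The default is deliberately small: planted "on"
  bonds (base distance ≤ 3.2 Å) then violate the 3.5 Å criterion with
  negligible probability, so detector-vs-truth comparisons are exact.
  Tests of the RMSF closed form use their own σ = 0.5 Å.
- **H-bond planting is geometric, not labelled**: an "on" instance has
  its donor hydrogen placed 1 Å from the donor along (or tilted up to
  35° from) the donor→acceptor axis; "off" returns the hydrogen to its
  inward resting direction. The tilt is planned once per instance so
  that the target angle stays above 145° while every *competing*
  acceptor near the donor stays below 123° — without this, a
  criterion-passing hydrogen aimed at O4 would often also "bond" the
  O3 sitting next to it, and the contamination would depend on the
  stacking geometry. If a planted pair's jittered donor–acceptor
  distance exceeds 3.5 Å the instance is recorded as off for that
  frame, so the ground truth describes the frame as built.
- **instance disjointness**: a donor hydrogen matched by several pair
  types (the amine N serves both N′H–O6 and N′H–O4) is assigned to one
  of them, alternating within each conflict group; the truth record
  carries the assigned instance tables.
- **bridge sites** pair two chitosan acceptors 4.6–6.2 Å apart across
  sheets 2/3 (water at the midpoint) or 4.0–5.4 Å apart within a sheet
  (water offset 1.8 Å out of the crowded sheet plane, on the side away
  from the interior slab). Sites are accepted only if the placed
  water's hydrogens cannot reach the angle criterion with any
  non-partner acceptor. Each surviving bridge contributes exactly two
  chitosan–water bonds and one bridge; expelled waters are parked in
  the bulk region.
- **interior waters** are placed uniformly in the slab with a 2.0 Å
  steric floor and *orientation rejection*: orientations are resampled
  until neither hydrogen can satisfy the angle criterion with any
  nearby acceptor, so interior waters never contaminate bridge or
  chitosan–water counts.
- **bulk waters** sit on a grid ≥ 12 Å beyond the fibril with dipole
  directions drawn from the axial distribution at the configured κ
  about the field axis (isotropic at κ = 0).
- determinism: the full output is a pure function of (fibril, config,
  seed); the caller's RNG state is saved and restored.

`generate_dewetting_scenario()` pairs a stationary "field-off" arm
(broad interior hydration, isotropic bulk dipoles, bridge survival
0.9) with a "field-on" arm (raised inter-chain occupancies, stacking
schedule ramping down by 0.6 Å — the centre of the reported 0.5–0.7 Å
contraction range — decaying interior water 30 → 5, bridge survival
0.35, κ = 2 field-aligned bulk dipoles). These planted values are
qualitative analogues of the published field effects, not
reproductions: the real effect sizes come from microsecond MD and are
out of reach at desk scale. A green scenario test establishes that the
estimators recover what was planted — not that the physics would
produce those numbers.

# Numerical choices and limitations

- Criterion comparisons are strict (< 3.5 Å, > 135°), matching the
  stated definitions; boundary ties are measure-zero.
- Occupancy pooling is the mean over instances; run-wise pooling over
  multiple trajectories is left to the caller (both conventions exist
  in the literature and the source data does not disambiguate).
- The brute-force O(N²) H-bond oracle used in the tests shares only
  the hydrogen→parent naming rule with the production detector.
- Chain ids beyond 26 chains are generated as AA, AB, … but the PDB
  writer truncates chain ids to one character; fibrils larger than 26
  chains should use the DCD/JSON route.
- Waters are identified by residue name `HOH` with atoms O/H1/H2; no
  other solvent models are recognised.
- The hull is exact for the given points; no probe radius, so this is
  neither a solvent-excluded nor a Voronoi volume.
- The toy charge set supports machinery tests only; any quantitative
  dipole statement about real chitosan requires the user's force-field
  charges via `read_charge_table()`.
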
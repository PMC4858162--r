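---
title: "Clamp ring geometry and coarse-grained ring opening"
author: "clampring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clamp ring geometry and coarse-grained ring opening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampring)
```

## The system and the descriptors

DNA sliding clamps are toroidal oligomers — homodimers of three-domain
protomers in bacteria (Pol III β), homotrimers of two-domain protomers in
phages (gp45) and eukaryotes (PCNA) — so every clamp is a pseudo-six-fold
ring of six structurally equivalent "DNA-clamp" domains.  Clamp loaders must
open one inter-protomer interface to thread the ring onto primed DNA, and
the open forms of different clamps differ: some stay planar, some form
out-of-plane spirals of either handedness, some reclose.

This package describes those conformations through the geometry of the six
domain centres of mass (COMs): adjacent COM distances, the COM angle at
each domain, and the signed COM torsion angles spanning an opened
interface.  For a clamp opened at one interface, three consecutive
four-domain windows around that interface define three torsions (for the β
clamp opened at A3/B1: B1–B2–B3–A1, B2–B3–A1–A2, B3–A1–A2–A3).  Their sum,
the **handedness sum**, is zero for a planar ring, positive for a
right-handed spiral of the COMs and negative for a left-handed one.

Conventions, fixed once and regression-locked by tests:

* **Dihedral sign** is the IUPAC right-handed convention (cis = 0,
  trans = 180°, values in (−180°, 180°]).  Rotating the fourth point by +α
  about the axis from point 2 to point 3 increases the dihedral by exactly
  +α; a chain of positive torsions traces a right-handed helix, which is
  what makes "positive handedness sum = right-handed spiral" hold.
* **COMs are mass-weighted** over non-hydrogen atoms (crystal structures
  carry no hydrogens).  Whether geometric or mass-weighted centres are used
  changes the angles by fractions of a degree for compact domains; a
  `method = "calpha"` switch is provided for robustness comparisons.
* **Angular time series are unwrapped** by nearest-image continuation
  (±360° to minimise frame-to-frame jumps) before averaging, because
  steered torsions can cross the ±180° branch cut.
* **Summaries discard the first 10 ns** (`discard_ps = 10000`) as
  pre-equilibration and report mean ± sample SD (n − 1).  Frames without
  time stamps require an explicit `discard_frames`.

### Inter-domain rotation

The rotation of one domain relative to a neighbour between a reference
conformation and a frame is computed from the two Kabsch rotations
`R_i`, `R_j` of the domains' own atoms: the relative transform
`R_rel = R_j R_iᵀ` has rotation angle `acos((tr R_rel − 1)/2)`, and the sign
is taken from the projection of its rotation axis onto the reference
inter-domain COM axis (i → j).  The exact construction is a design choice of
this package — equilibrium-simulation papers typically quote such rotations
without printing a formula — and is validated by *recovery*: the synthetic
generator injects known rotations about known axes and the pipeline must
return them (exactly without noise, to within sampling error with noise).
Note one convention subtlety: with this sign definition a right-handed
spiral can legitimately be reported with negative pairwise rotation values
depending on which neighbour is taken as `i`; published descriptions of
PCNA use the opposite sign to their own handedness plot.  We do not force
the two conventions to agree; the handedness sum is the canonical chirality
readout.

### RMSD100

Raw RMSD grows with assembly size, so fluctuation amplitudes of a monomer
and a trimer are not comparable.  The size-normalised
`RMSD100 = RMSD / (1 + ln(N/100))` rescales an RMSD over N residues to a
100-residue equivalent.  It is the identity at N = 100, monotonically
decreasing in N, and undefined below N ≈ 37 where the denominator becomes
non-positive (the package refuses such N).  The trajectory metric computes
it on Cα atoms after Kabsch superposition onto the first frame; Cα-only is
a default choice, not something the normalisation itself requires.

## Clamp topologies

A `clamp_topology` carries the domain labels, chain + author-numbered
residue range per domain, the cyclic ring order, the designated opening
interface and its three torsion quadruples.  Topology YAMLs for 1OK7 (β
dimer), 1JQL (β monomer; no opening interface), 1PLQ (PCNA) and 1B77
(gp45) ship with the package.  **The residue ranges are reconstructions**:
the publications behind these structures show the domain decomposition in
figures but never tabulate boundaries, so we use the standard fold
decompositions (β: 1–125/126–252/253–366 per protomer; PCNA: 1–117/118–258;
gp45: 1–110/111–228) and keep them user-editable.  Crystal-derived angle
checks therefore carry a ±2° tolerance for boundary ambiguity.

## The coarse-grained simulator

The ring-opening protocols act on COM-level collective variables, so they
can be exercised on a model that contains exactly those degrees of freedom:
one bead per clamp domain (the aggregate domain mass, ~1.3 × 10⁴ amu for a
~120-residue domain), harmonic bonds/angles/torsions between consecutive
beads with equilibrium values taken from the source conformation (the built
state has zero energy by construction), and the bonded set spanning the
opening interface removed.  This is a desk-scale surrogate: it reproduces
the steering mechanics and the restraint thermodynamics, not the atomic
interface chemistry that decides whether a real clamp recloses.

* **Units** are Å, ps, amu, kcal/mol with
  k_B = 0.0019872041 kcal mol⁻¹ K⁻¹ and 1 kcal/mol = 418.4 amu Å² ps⁻².
  Degree-based torsion force constants are converted internally by
  (180/π)².
* **Stiffness defaults** (bonds 10 kcal mol⁻¹ Å⁻², angles and torsions
  30 kcal mol⁻¹ rad⁻²) put thermal angular fluctuations at 310 K in the
  several-degree range seen for equilibrated clamp sub-assemblies; they are
  exposed through `cg_stiffness()`.
* **Integrator**: BAOAB Langevin splitting, 10 fs timestep, damping
  5 ps⁻¹, temperature 310 K.  At T = 0 with zero damping it reduces to
  velocity Verlet and conserves energy to < 10⁻⁶ kcal/mol per step, which
  the suite checks; a diverging T = 0 energy raises an integration error
  advising a smaller step.  All randomness flows through R's RNG, so a
  seed fixes the trajectory bitwise.
* **Restraints** use U = (k/2)(ξ − ξ₀(t))² with ξ₀ moving linearly during
  the steering phase.  Published colvar setups are ambiguous about the ½
  factor; fixing it makes target-tracking and equipartition checks
  self-consistent, which is all that matters here.  Torsion differences are
  wrapped to (−180°, 180°]; the 1/sin² factor in the torsion gradient is
  capped so near-collinear geometry can never produce NaN forces (CG rings
  never approach collinearity in normal operation).
* **Schedules**: type 1 pulls the interface COM distance at 2 Å/ns under
  k = 500 kcal mol⁻¹ Å⁻² for +20 Å over 10 ns; types 2/3 drive the three
  interface torsions by −20°/+20° under k = 50 kcal mol⁻¹ deg⁻².  Torsion
  targets are assumed to move linearly like the distance target (the
  published protocol states linearity only for the distance).  After
  steering, restraints are released; the free phase defaults to 10 ns for
  desk-scale runs (the published schedule used 140 ns, available via
  `post_steering_ps`).  CG relaxation times map onto no particular all-atom
  nanosecond; CG "ns" are nominal.

Because the bead model's equilibrium geometry *is* its reference
conformation, free relaxation is informative only about the machinery: a
system built from a planar ring relaxes to handedness ≈ 0, one built from a
right-handed spiral to a positive sum.  The suite asserts exactly this
mechanistic mirror of the reclosing-vs-staying-open contrast and nothing
more; the CG model cannot adjudicate which real clamp does which.

## The synthetic generator

`build_ideal_ring()` constructs the testbed: six rigid anisotropic
pseudo-atom clouds (anisotropic so orientation fits are unique) whose COMs
sit on a 35 Å circle — clamp-sized, planar, hexagonal.  Deformations are
applied as exact rigid per-domain transforms:

* spiral modes rotate successive domains about the interface COM axes so
  each designated torsion changes by *exactly* the requested twist
  (processed window by window, so the changes compose exactly and are
  exactly invertible);
* `planar_open` translates the half-ring on one side of the open interface
  along the interface axis, widening the gap by exactly the requested
  amount while staying planar;
* `in_plane_angle` hinges the outer domains about a chosen middle domain in
  the ring plane, changing that COM angle by exactly the increment — the
  in-plane monomer opening motif (a ~7° opening of the β monomer's
  A1–A2–A3 angle is the observed magnitude this mimics).

`generate_trajectory()` emulates an equilibrated sub-assembly
statistically: per frame, a designated neighbour domain is rigidly rotated
about the reference inter-domain axis by an i.i.d. Normal(μ, σ²) draw
(defaults μ = 13.9°, σ = 4.4°, the reported gp45-monomer inter-domain
rotation distribution), plus isotropic Gaussian coordinate noise; the exact
draws are recorded as ground truth.  What this does **not** emulate:
correlated frame-to-frame dynamics, anharmonicity, multi-interface
coupling, internal domain deformation, sequence or secondary structure.
Passing recovery tests therefore demonstrates that the analysis pipeline is
unbiased and correctly signed for rigid-body motion — not that it would be
noise-free on real all-atom output.

Left/right spiral outputs are mirror images at the COM level (the z-flipped
right-handed COMs superpose on the left-handed ones to machine precision,
and the handedness sums negate exactly); the pseudo-atom clouds themselves
are chiral objects, so the mirror property is asserted on COMs, which is
what the handedness metric reads.

## Problem sizes and numerical tolerances

The suite and the acceptance script run entirely from generated inputs:
10⁶-step (10 ns) steered runs for the type-1/2 endpoint checks, a 10⁶-step
equipartition run (stationary torsion variance k_BT/k within 20%,
Monte-Carlo error at these lengths is ~1%), 1000-frame recovery
trajectories (3-standard-error band ±0.42° on the 13.9° mean), 1000-case
oracle sweeps for dihedral and Kabsch (10⁻⁹ agreement against an
independent acos/atan2 formulation and a quaternion eigenvalue method), and
200-state central-difference force checks (< 10⁻⁵ relative).  Exact
constructions (deformations, round trips) are asserted at 10⁻⁶–10⁻⁹;
PDB round trips at the format's 10⁻³ Å precision.

Checks that need the crystal structures (the 123.1°/120.5°/119.3° COM
angles and the ~5° monomer opening) download 1OK7, 1PLQ and 1JQL via
`fetch_pdb()` at run time — the entries are too large to ship — so that
part of the suite requires network access and fails cleanly without it.

## Known limitations

* The CG simulator has no excluded volume, no electrostatics and no
  interface chemistry; steered endpoints and restraint statistics are
  meaningful, spontaneous-opening propensities are not.
* Domain boundaries in the shipped topologies are reconstructions (above).
* Multi-model PDB is the only trajectory dialect read natively; binary
  trajectory formats should be converted upstream.
* `rmsd100` is undefined below 37 residues by construction of the formula.
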
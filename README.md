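# clampring

Geometry and coarse-grained ring-opening dynamics of DNA sliding clamps.

Sliding clamps — bacterial Pol III β, bacteriophage gp45, eukaryotic PCNA —
are pseudo-six-fold protein rings that encircle duplex DNA and tether
polymerases and repair enzymes.  Loading them onto DNA requires opening one
inter-subunit interface, and open clamps differ structurally: planar open
rings, right-handed spirals, left-handed spirals, or reclosing rings.
`clampring` is for structural bioinformaticians and simulators who want to
quantify those conformations from structures and trajectories, and to
exercise the steered ring-opening protocols on a desk-scale model.

The descriptors are built from the centres of mass (COMs) of the six clamp
domains:

* adjacent COM **distances** and the COM **angle** at each domain
  (the in-plane opening coordinate);
* the three signed COM **torsions** spanning the opened interface
  (IUPAC sign convention); their sum, the **handedness sum**, is 0 for a
  planar ring, > 0 for a right-handed spiral, < 0 for a left-handed one;
* **inter-domain rotations** from Kabsch body-frame fits,
  `angle(R_j R_iᵀ)` with the sign of the rotation axis projected on the
  inter-domain axis;
* size-normalised RMSD, `RMSD100 = RMSD / (1 + ln(N/100))`.

A one-bead-per-domain Langevin simulator (BAOAB, 10 fs step, 310 K,
damping 5 ps⁻¹) implements the three steered opening protocols as moving
harmonic restraints `U = (k/2)(ξ − ξ₀(t))²`:

| type | collective variable | schedule |
|------|--------------------|----------|
| 1 | interface COM distance | +20 Å at 2 Å/ns, k = 500 kcal mol⁻¹ Å⁻² |
| 2 | three interface torsions | −20° each over 10 ns, k = 50 kcal mol⁻¹ deg⁻² (left-handed spiral) |
| 3 | three interface torsions | +20° each (right-handed spiral) |

A synthetic clamp generator supplies planar rings, exact spiral/open/hinged
deformations and Gaussian-rotation trajectories with recorded ground truth,
so the whole pipeline is testable without downloads.  The sphere-and-arrow
representation (one sphere per domain COM plus a body-fixed orientation
arrow) is included for visualising domain reorientation.

## Worked example

```r
library(clampring)

ring <- build_ideal_ring(seed = 1)            # 6 domains on a 35 A circle
asg  <- assign_domains(ring$structure, ring$topology)
ring$topology
#> <clamp_topology> synthetic_ring: 6 domains [A1,A2,A3,B1,B2,B3], open interface B3/A1

# inject a right-handed spiral: +20 deg at each interface torsion
spiral <- apply_deformation(ring$structure, ring$topology, "rh_spiral", twist = 20)
handedness_sum(spiral, asg, ring$topology)
#> [1] 60

# steer the planar ring open as a left-handed spiral (type 2), 10 ns
sys   <- build_cg(ring$structure, asg, ring$topology)
proto <- make_protocol(2, ring$topology, post_steering_ps = 0)
traj  <- run_steered(sys, proto, langevin_params(seed = 1))
cv    <- colvar_table(traj)
subset(cv, time_ps == 10000)[, c("restraint_id", "value", "target")]
#>  restraint_id     value target
#>             1 -19.94947    -20
#>             2 -20.21647    -20
#>             3 -20.06647    -20
tail(cg_handedness_series(traj)$values, 1)
#> [1] -60.23241
```

Each steered torsion ends within a fraction of a degree of its −20° target
(the residual is the thermal fluctuation, sd ≈ `sqrt(kT/k)` ≈ 0.11°), and
the handedness sum lands at −60°: a left-handed spiral by construction.
With a free-relaxation phase appended (`post_steering_ps = 10000`), the
restraints are released and this system — whose bonded equilibria encode
the planar ring — flattens back toward handedness 0.

Crystal-structure geometry uses the same machinery plus a shipped topology,
e.g. `cmd_analyze(fetch_pdb("1ok7"), default_topology("1ok7"),
"angle:A1,A2,A3", ...)` (network required; domain residue ranges in the
shipped topologies are documented reconstructions).

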
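---
title: "Screw geometry and the construction of filamentous protein assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screw geometry and the construction of filamentous protein assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Many proteins self-assemble into filaments, helices and rings through a
single repeated monomer–monomer interface.  Any rigid placement of one
monomer copy relative to another is a screw transformation: a rotation by
an angle $\theta$ about an axis (point $O$, unit direction $\Omega$)
combined with a translation *trans* along that axis.  Repeating the
transformation generates the whole assembly, so one pairwise binding
geometry determines a unique regular architecture with global parameters

$$N = 360/\theta, \qquad P = N \times |trans|, \qquad
  dir = \mathrm{R} \text{ if } \theta \cdot trans > 0,\ \mathrm{L}
  \text{ otherwise},$$

where $N$ is the number of monomers per turn and $P$ the pitch in
&Aring;ngstr&ouml;m.  `trans` $\approx 0$ gives closed rings (cyclic
symmetry $C_k$), $\theta \to 0$ gives straight filaments.  Bacterial
recombinase (RecA-type) filaments are the motivating system: their
compressed (ADP) and extended (ATP) fiber forms correspond to two distinct
interface geometries of the same monomer, both right-handed, with roughly
6 and 6.2 monomers per turn.

The package implements the full analysis loop:

1. **Extraction** (`screw_from_transform()`, `screw_between_monomers()`):
   the screw parameters of the transform relating two monomer copies,
   obtained analytically from the least-squares (Kabsch) superposition.
2. **Construction** (`build_filament()`, `build_mixed_filament()`,
   `build_on_curve()`, `build_supercoiled_pair()`): assemblies of arbitrary
   length from one or several interface screws, along straight or curved
   axes.
3. **Discovery** (`dock()`, `filter_poses()`): coarse-grained rigid-body
   self-docking proposes candidate interfaces; each minimized pose is a
   candidate assembly geometry.
4. **Classification and adjustment** (`classify_geometry()`,
   `adjust_to_cyclic()`, `steric_screen()`): each geometry is assigned to
   the Filament / Cyclic / NearCyclic / NearHelical zones of the $(N, P)$
   plane; near-cyclic geometries are pushed onto exact ring symmetry;
   near-helical ones are screened for cross-turn steric clashes.
5. **Metrics** (`contacts()`, `fnat()`, `fir()`, `rmsd()`, `sasa()`,
   `buried_surface()`, `groove_width()`): interface similarity and
   morphology descriptors.
6. **Family exploration** (`explore()`): contact-constrained Metropolis
   Monte Carlo maps the variability of one binding mode.

## Parameters that matter

* **Energy window, 20 RT.**  After docking, poses within 20 RT of the
  reference (or best) interaction energy are retained.  The window is wide
  on purpose: the docking unit is a rigid core with flexible regions
  removed, and their missing contribution introduces an uncertainty of
  this order.
* **Classification thresholds.**  Filament if $P > 2 R_M$ where $R_M$ is
  the maximum monomer radius (no cross-turn contact is then possible);
  Cyclic if $N$ is within $\pm 0.1$ of an integer and $|P| \le 0.5$ Å;
  NearCyclic if $P < (N-1) \times 5$ Å, i.e. accepting an axial closure
  error of up to 5 Å per interface; NearHelical otherwise.  $R_M$ is
  measured from the monomer centroid, a deterministic choice the
  classification rule itself does not fix.  $|P|$ is used (the screen is
  insensitive to handedness).
* **Force field.**  $E = \sum A_{ij}/r^8 - B_{ij}/r^6 +
  q_i q_j/(\varepsilon_0 r \cdot r)$ over bead pairs within a 20 Å cutoff:
  a smooth 6–8 van der Waals term plus a Coulomb term screened by a
  distance-dependent dielectric $\varepsilon(r) = \varepsilon_0 r$ with
  $\varepsilon_0 = 15$ by default.  The published engine's bead-type
  tables are not public, so coefficients derive from a small per-class
  table (radius $R_b$, well depth $\epsilon_b$ in RT) with
  Lorentz–Berthelot-style combination, $A = 3\epsilon r_m^8$,
  $B = 4\epsilon r_m^6$, $r_m = R_i + R_j$, giving a well of depth
  $\epsilon$ exactly at $r_m$.  Everything is overridable via
  `forcefield_params()` or a JSON file.  Energies are reported in RT at
  300 K.  Pair distances are evaluated with a soft cap at 1 Å (pairs
  below 0.1 Å flag the pose as capped) so clashed starts stay finite.
* **Coarse graining.**  One backbone bead (N, C$\alpha$, C, O centroid)
  plus up to two side-chain beads split at the $\gamma$ position — about
  four heavy atoms per bead.  Asp/Glu and Lys/Arg distal side-chain beads
  carry $\mp 1$ elementary charge.
* **Docking starts.**  Global mode places ligand centers on a
  quasi-spherical Fibonacci shell at constant surface-to-surface distance
  with ~10 Å spacing and 6 deterministic orientations per point (the
  original protocol does not publish its orientation count; 6 is the
  package default and configurable).  Targeted mode uses a 2 Å cubic grid
  within 20 Å of the reference ligand's center of mass.  Minimization is
  BFGS over the six rigid-body degrees of freedom with analytic
  force/torque gradients.
* **Monte Carlo.**  $10^5$ steps by default at 300 K, uniform proposals of
  $\pm 5^\circ$ per rotational variable and $\pm 3$ Å per translation, and
  a hard constraint $f_{NAT} > 0.5$ against the reference contact set;
  constraint violations count as rejections in the reported acceptance
  rate (the alternative bookkeeping is not documented in the original
  protocol).  Descriptors (energy, $N$, $P$, handedness, ligand RMSD,
  $f_{NAT}$, $f_{IR}$) are recorded at every step.
* **Contacts.**  A residue pair is a contact when any two heavy atoms are
  closer than 5.0 Å (the community-standard native-contact criterion; the
  original definition is in an unavailable protocol supplement, which is
  why contact-derived checks carry a $\pm 0.05$ tolerance).  On
  coarse-grained beads a 7 Å cutoff is the working equivalent.
* **SASA.**  Shrake–Rupley sphere sampling, 960 points per atom, probe
  1.4 Å, van der Waals radii from a built-in element table.  Buried
  surface area is the ASA lost on complexation, per monomer.  Region
  contributions use the truncation scheme (recompute after deleting a
  region, subtract); an exactly additive per-atom decomposition is also
  provided (`method = "atomic"`) because truncation additivity is only
  approximate.
* **Groove width.**  Radial reference shells every 1 Å between
  $(r + R)/2$ and $R$, azimuthal stations every $0.5^\circ$; per station
  the protein-free axial gaps between successive turns are measured on
  the central one-pitch window.  The per-angle aggregation over shells
  (mean, with min and max also exported) is a package choice; the original
  protocol text is not available.

## Design choices made where the design was open

* **Screw conventions.** $\theta \in (0, 180]$, handedness carried by the
  sign of `trans`; the axis point is the perpendicular foot of the origin,
  making outputs unique and testable.  Rotations below $0.1^\circ$ are
  flagged pure translations ($N = \infty$, classified Filament); at
  $\theta = 180^\circ$ the axis sign is fixed by a deterministic rule.
* **Cyclic adjustment.**  The protocol supplement describing the original
  Monte-Carlo adjustment is unavailable.  Here: low-temperature Metropolis
  minimization of interaction energy plus ramped harmonic restraints
  $w_\theta(\theta - 360/k)^2 + w_t\,trans^2$, followed by exact projection
  of the final screw onto $(\theta = 360/k,\ trans = 0)$.  The
  post-condition (ring closure) therefore holds exactly, and the ring
  gallery entries re-classify as Cyclic.
* **Curved-axis construction.**  A rotation-minimizing (double-reflection)
  frame along the guide curve, with the per-step twist re-applied about
  the local tangent.  A Frenet frame would blow up at inflection points;
  the rotation-minimizing frame reproduces the straight-line limit exactly
  and distributes torsional deformation evenly, which is what the
  supercoiled construction requires.  Validated through the straight-limit
  identity and toroid closure, since the original construction protocol is
  not published in the main text.
* **Configuration files** use JSON rather than YAML because the target
  R environment provides a JSON parser only.

## What the synthetic generator does and does not establish

`make_toy_monomer()` builds deterministic pseudo-proteins (compact
solenoid "blob", straight "rod", arc "horseshoe") with backbone-like atoms
and 1–2 side-chain pseudo-atoms per residue; residue names cycle through
charged and neutral types so coarse-graining, electrostatics and pruning
are all exercised.  `make_assembly_fixture()` places copies by a known
screw with optional per-interface jitter, recording the ground truth.

These fixtures make every stage testable without downloads: screw
round-trips, ring closure, classification zones, docking-site recovery
(via an engineered charge-complementary horseshoe whose global energy
minimum is unambiguous), and the Monte-Carlo constraint and dispersion
properties (a C6 ring of compact monomers placed 24 Å off-axis, chosen
once so the geometric ring is genuinely bound rather than clashed).  They
do **not** emulate real protein shape complementarity, side-chain packing
or electrostatic heterogeneity, so a green synthetic suite establishes
correctness of the geometry, bookkeeping and sampling machinery — not
predictive docking accuracy on real structures.  The crystal-structure
checks (RecA pitch 85/94/74 Å, core RMSD 0.89 Å, $f_{NAT}$ 0.34/0.9/0.0,
mixed-mode super-helix 312 Å and alternating 82 Å fibers) are implemented
in the acceptance suite and run whenever the PDB entries 2REB, 3CMW and
1U94 are supplied; they cannot run in an offline build and are reported
as failing there by design.

## Known limitations

* Docking energies are not comparable to the published engine's values
  (different bead tables); only geometric/recovery properties are
  asserted.
* Flexible-monomer docking, multi-interface optimization of clashed
  near-helical geometries, free-energy ranking of binding modes and DNA
  placement are out of scope.
* The per-interface energy convention for $C_2$ dimers (halving the
  pairwise value, since the two monomers of a dimer share both ring
  interfaces) is applied in the workflow's signature table only; raw pose
  energies are never rescaled.
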
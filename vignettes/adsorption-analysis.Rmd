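---
title: "Methods: protein adsorption and denaturation analysis on 2H-MoS2 monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein adsorption and denaturation analysis on 2H-MoS2 monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoadsorb)
```

`nanoadsorb` implements the computational machinery used to characterise how
a small helical protein adsorbs onto, and is denatured by, a two-dimensional
transition-metal-dichalcogenide monolayer. It covers three layers of work:
system construction (the monolayer builder and protein placement), the
trajectory observables (contacts, native-contact fraction, secondary
structure, energetics, hydration, kinetics), and a synthetic-trajectory
generator that makes every observable testable against exact ground truth
without running molecular dynamics. This vignette records the models, the
tunable parameters, and the design decisions.

## The monolayer model

A 2H-MoS2 monolayer is a tri-atomic S-Mo-S sandwich: molybdenum atoms on a
hexagonal plane, sulfur planes offset vertically by `dz` on either side, each
Mo coordinated by six S (three up, three down) in a trigonal prism. The
builder uses a rectangular (orthorhombic) cell with vectors $(a, 0)$ and
$(0, a\sqrt3)$ containing 2 Mo and 4 S; x is the zigzag direction. A patch of
`nx` by `ny` cells therefore has extents $(n_x a,\; n_y a\sqrt3)$ and
$6\,n_x n_y$ atoms, with every Mo-S bond equal to $\sqrt{a^2/3 + dz^2}$.

Defaults are `a = 0.316` nm and `dz = 0.1564` nm, the standard 2H-MoS2
crystallographic values; both are arguments of `lattice_spec()` because
published force fields differ slightly. Because a requested size such as
6.735 x 6.600 nm is generally incommensurate with the lattice,
`monolayer_for_extents()` picks the repeats minimising the per-axis error and
reports the achieved extents (21 x 12 cells, 6.636 x 6.568 nm for that
target) — always within half a lattice spacing per axis.

Nonbonded parameters (sigma nm, epsilon kcal/mol, charge e per species) are
configuration data, never hard-coded: `inst/extdata/mos2_params.yml` ships a
widely used MoS2 set (Mo +0.6 e, S -0.3 e, neutral per MoS2 unit) explicitly
labelled provisional, to be replaced by whatever parameterisation a user's
own simulations employ. The sheet is treated as rigid; its `frozen` flag is
metadata propagated to an index-group file, not dynamics.

## System setup

`place_protein()` is a pure rigid-body move: the protein's xy centroid is
aligned over the sheet centre and the chain is translated along z until the
*minimum distance from any protein heavy atom to any sheet atom* equals the
requested gap (0.8 nm in the headline setup). The sheet-side atom set (S and
Mo alike) is part of the definition and is recorded in the output, because
"distance to the surface" is otherwise ambiguous. The vertical offset is
solved in closed form (per-pair lateral distances are fixed under a z
translation), so the realized gap is exact to floating-point precision and
placement is idempotent.

Formal charge uses standard protonation at pH 7: Asp/Glu -1, Lys/Arg +1, His
neutral, zwitterionic termini net 0. For the 35-residue headpiece sequence
(residues 42-76) this gives +2, hence two chloride counterions — the check
that pins the package's charge bookkeeping to the published system
composition. Water insertion is deliberately out of scope: solvent counts
depend on the solvation tool, so `suggest_box()` and `setup_report()` only
provide the box and counts an engine-level tool needs.

## Trajectory model and I/O

Coordinates are nm everywhere internally; PDB Angstroms are converted on
read/write. Residue numbering is kept verbatim from input files (the
headpiece runs 42-76), so literature residue labels match directly.
Hydrogens, when present, are retained but excluded from every contact
criterion by the `heavy` flag. The minimum-image convention applies only when
a frame carries a box; otherwise coordinates are assumed unwrapped.

Readable formats are PDB/GRO structures and multi-model PDB or DCD
trajectories. XTC/TRR readers do not exist in the R ecosystem this package
builds on, so those formats raise an informative error; the generator writes
multi-model PDB, which round-trips frame times through `REMARK t=` lines.

The selection grammar (`protein`, `water`, `sheet`, `heavy`, `sidechain`,
`backbone`, `resid A-B`, `resname X`, `and`/`or`/`not`, parentheses) exists
so that the contact atom set of the analyses — `protein and sidechain and
heavy` — is an explicit, testable expression rather than an implicit
convention.

## Observables

**Contacts.** An adsorption contact counts a protein sidechain heavy atom
with any sheet atom within `rc_contact = 0.6` nm. The count convention is
*atoms in contact* (not pairs); a `pairs` flag exposes the alternative and
output headers label the convention, since both readings of a "contact
number" are in circulation.

**Native contacts and Q(t).** A native contact is a residue pair at sequence
separation >= 3 whose minimum heavy-atom distance in the reference structure
is <= 0.6 nm (the same cutoff as the sheet-contact criterion). Q(t) is the
fraction of those pairs still satisfied at time t; Q of the reference is 1 by
construction. The pair criterion uses *all* heavy atoms (backbone plus
sidechain) by default — a `part` knob restricts to sidechains — because the
contact definition used for the surface does not restrict the native-contact
side.

**Helix ratio.** Assignment is dihedral-window based: a residue is helical
when $(\phi, \psi)$ lies within +/-30 degrees of (-57, -47) *and* belongs to
a run of >= 4 consecutive such residues. This is deliberately not a full
secondary-structure algorithm (no DSSP reimplementation): the window and
run-length rule capture "fraction of residues in an alpha-helix" with two
transparent parameters, both configurable. Chain termini lack phi or psi and
are excluded from the denominator.

**Hydrogen bonds.** Geometric criterion: donor-acceptor distance (N/O heavy
atoms) <= 0.35 nm, plus a donor-H-acceptor angle >= 150 degrees when
hydrogens are present; without hydrogens the distance criterion alone is used
and the choice logged. Pairs within a residue, or between covalently adjacent
protein residues (whose backbone N/O sit at bonded distances), never count.
The headline quantity is the *ratio* to the reference-structure count, which
makes the absolute criterion less critical.

**Salt bridges and cation-pi.** A salt bridge is a basic sidechain nitrogen
(Arg NE/NH1/NH2, Lys NZ) within 0.4 nm of an acidic carboxylate oxygen; a
cation-pi stack is a cation group centre (Arg CZ, Lys NZ) within 0.5 nm of an
aromatic ring centroid (mean of ring-atom positions; Trp uses its
six-membered ring).

**Energetics.** Protein-sheet interaction energies are sums of 12-6
Lennard-Jones and Coulomb pair terms over cross pairs within
`rc_energy = 1.0` nm, Lorentz-Berthelot combination by default, negative =
attractive, kcal/mol externally (4.184 exactly). Electrostatics are *plain
truncated Coulomb*, optionally with a reaction-field correction
(`rf_epsilon`): this package evaluates energies on stored frames, not forces
for dynamics, so a lattice-sum treatment would add complexity without
changing what the decomposition is for — ranking residues. The per-residue
maps partition the totals exactly (tested to 1e-6 kcal/mol). Tail averages
("last N ns") report a 5-block standard error; the estimator is recorded in
the output because published +/- values rarely say which estimator they are.
The favorable-residue filter keeps residues below -20 kcal/mol.

**Hydration and kinetics.** The first solvation shell of a residue is the
set of water oxygens within `rc_fss = 0.45` nm of its sidechain heavy atoms;
the cutoff is a package default (a typical first-minimum distance of
water-carbon radial distributions) and is configurable — absolute shell
counts always depend on it, which is why the package treats published counts
as semantic anchors rather than test targets. The dewetting count uses an
axis-aligned prism between the top sulfur plane and the residue's lowest
heavy atom (bounding box + 0.3 nm padding): deterministic and transparent,
at the cost of overcounting versus a convex hull. First-contact times
require `persistence_k = 5` consecutive frames of contact so single-frame
grazing encounters do not define an onset; helices are ordered by the
earliest onset among their residues, ties broken by helix index. The
adsorption-denaturation link is the Pearson correlation between the contact
count and 1 - Q.

## The synthetic-data generator

The generator exists because the study-scale trajectories (hundreds of ns of
solvated all-atom dynamics) cannot be recomputed or redistributed at desk
scale. It does *not* integrate equations of motion; it constructs every frame
from a scenario recipe, which is exactly what makes its ground truth exact:

* **Ideal bundle.** Backbone N/CA/C/O chained with ideal internal
  coordinates; phi/psi are (-57, -47) inside the three helix spans (43-52,
  54-61, 62-74) and (-120, +120) in loops. Sidechains are a CB atom plus a
  pseudo-atom cluster sized to the residue's true heavy-atom count — contact,
  hydration and energy metrics need heavy-atom positions and counts, not
  rotamers. Formal charges sit on terminal sidechain pseudo-atoms and the
  termini, so the chain's net charge matches the sequence (+2).
* **Melting.** Helix melting sets phi/psi to the coil values by rotating the
  downstream block rigidly, which provably leaves every other residue's
  internal geometry untouched. The default schedule melts helix 2 before
  helix 3 and leaves helix 1 intact; a melt-fraction helper consumes helices
  in the order 2, 3, 1, each from its C-terminal end, so the >= 4-run helix
  rule tracks 1 - m to within one residue of the denominator.
* **Contacts.** The rigid-body gap schedule descends from 0.8 nm to 0.65 nm
  — just above the 0.6 nm cutoff — so *only* programmed residues ever touch
  the sheet. At its onset time (snapped to the frame grid; snapped values are
  the truth) a residue's sidechain is pinned into a thin slab 0.35-0.50 nm
  above the top sulfur plane and clamped laterally into the sheet footprint,
  guaranteeing contact under the 0.6 nm criterion at every subsequent frame.
* **Hydration.** Shell waters are single oxygen sites placed within the
  stated radius (0.42 nm < rc_fss) of the target residue's sidechain,
  rejection-sampled outside a 0.25 nm core, clear of other targets' shells
  and of the sheet, with exact per-frame counts; a dewetting time drops the
  count to its post-adsorption value. The default scenario dries the
  aromatic target from 18 to 6 waters and the basic target from 18 to 12 —
  the qualitative asymmetry expected between a hydrophobic ring that lies
  flat and a charged group that stays partly hydrated.
* **Determinism.** All randomness flows from one integer seed, re-derived
  per frame (seed below 2^31), so frame access order cannot change results
  and identical seeds give byte-identical trajectories.

The default scenario compresses the phenomenology into a 20 ns window
sampled every 200 ps (101 frames): anchoring order helix 2 -> 1 -> 3,
helix 2 melting before helix 3, dewetting late in the window. The native
20 ps output spacing of production simulations is honoured as trajectory
metadata, not as the generator default, which keeps the synthetic problem
desk-sized.

What the generator does *not* emulate: physical forces and thermal noise,
realistic unfolding pathways, water structure beyond counted shells,
quantitative energy scales of fully adsorbed states (no synthetic residue
reaches the -20 kcal/mol favorable threshold, and the scripts say so). A
passing test suite therefore demonstrates that the *analysis* machinery is
exact and self-consistent — not that a particular physical system behaves a
particular way.

## Numerical choices

* Pair distances are evaluated as dense vectorized matrices rather than via
  a cell list: at the package's problem sizes (10^3-10^4 atoms) this is
  faster in interpreted code and has no approximation to get wrong;
  correctness is pinned to exhaustive O(N^2) oracles in the test suite.
* The placement solve is closed-form (max over pairs of the per-pair
  vertical shift), not iterative.
* LJ and Coulomb evaluation excludes r = 0 by construction and errors on
  non-positive distances at the scalar API.
* Angle arithmetic uses a minimal-image difference on the circle, so the
  +/-30 degree window behaves correctly near the -180/180 seam.
* TSV outputs are written with a fixed `%.10g` format and `# convention:` /
  `# config:` headers, making identical configurations byte-identical — the
  determinism contract is tested, not assumed.

## Problem sizes

The test suite runs oracle equivalences on random systems of up to a few
hundred atoms (100 seeds per metric family), ground-truth recovery on 20
random scenarios of 21 frames each, and pipeline determinism on a reduced
21-frame scenario; the acceptance script runs the full 101-frame default
scenario over the 1512-atom target sheet. These sizes are the package's
choice of a thorough-but-snappy regression envelope; every computation
scales to longer real trajectories through the same functions.

## Known limitations

* No XTC/TRR input; convert to DCD or multi-model PDB upstream.
* Truncated (or reaction-field) electrostatics, not a lattice sum: absolute
  electrostatic totals on charged systems carry cutoff artifacts, and the
  package's electrostatic numbers should be read comparatively.
* The helix assignment is a two-parameter dihedral rule, not DSSP; beta and
  turn classes are out of scope.
* The dewetting prism overcounts relative to a convex hull.
* Pseudo-atom sidechains reproduce counts and gross geometry, not rotamer
  detail; detectors requiring named atoms (salt bridge, cation-pi) are
  exercised on micro-fixtures with real atom names instead.
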
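# nanoadsorb

Analysis toolkit for protein adsorption and denaturation on 2D
transition-metal-dichalcogenide nanosheets, built around the villin
headpiece subdomain (HP35, a 35-residue three-helix bundle, residues
42-76) on a 2H-MoS2 monolayer. It is aimed at molecular-simulation
practitioners who need to (i) construct engine-ready monolayer/protein
systems and (ii) compute the standard adsorption observables on
trajectories — plus a deterministic synthetic-trajectory generator so that
every observable is testable against exact ground truth without running MD.

## What it computes

* **Monolayer builder** — orthorhombic 2H-MoS2 patches: cell $(a,0) \times
  (0,a\sqrt3)$ with 2 Mo + 4 S, S planes at $\pm dz$, every Mo-S bond
  $\sqrt{a^2/3+dz^2}$; nonbonded parameters (sigma, epsilon, charge per
  species) from a YAML config; PDB/GRO output plus a frozen-atom index
  group.
* **System setup** — rigid placement of a protein at a prescribed minimum
  heavy-atom gap above the sheet (default 0.8 nm), formal charge at pH 7
  (Asp/Glu -1, Lys/Arg +1, His 0, zwitterionic termini) with counterion
  counts, and box suggestion.
* **Structural metrics** — sidechain-heavy-atom contact counts with the
  sheet (cutoff 0.6 nm); native contacts (residue pairs, separation >= 3,
  min heavy-atom distance <= 0.6 nm in the reference) and the retained
  fraction Q(t); dihedral-window alpha-helix ratio (phi/psi within 30 deg
  of (-57,-47), runs >= 4); hydrogen-bond counts/ratios (0.35 nm, 150 deg);
  salt-bridge (0.4 nm) and cation-pi (0.5 nm) detectors; hydrophobic
  percentage of residue sets.
* **Energetics** — protein-sheet Lennard-Jones
  $4\varepsilon[(\sigma/r)^{12}-(\sigma/r)^6]$ and truncated Coulomb
  $k q_i q_j / r$ pair sums (cutoff 1.0 nm, Lorentz-Berthelot, kcal/mol,
  negative = attractive), exact per-residue decomposition, trailing-window
  averages with block-averaged standard errors, favorable-residue filter
  (< -20 kcal/mol).
* **Hydration & kinetics** — first-solvation-shell water counts (oxygens
  within 0.45 nm of sidechain heavy atoms), dewetting-slab counts, first
  persistent contact times, helix anchoring order, adsorption-denaturation
  correlation (contacts vs 1 - Q).
* **Synthetic scenarios** — ideal three-helix bundle, programmed approach /
  per-residue contact onsets / helix melting / shell-water schedules, with
  exact per-frame ground truth for every stage.

## Worked example

```r
library(nanoadsorb)

# 1. Monolayer at the headline target size
sheet <- monolayer_for_extents(6.735, 6.600)
#> target extents (6.735, 6.600) nm -> 21 x 12 cells, achieved (6.636, 6.568) nm
range(mo_s_bonds(sheet))       # all six bonds per Mo identical
#> [1] 0.2403046 0.2403046

# 2. Charge bookkeeping for the headpiece sequence
formal_charge(hp35_sequence())  # => 2, i.e. two chloride counterions
#> [1] 2
hydrophobic_fraction(c("Arg-55","Phe-58","Asn-60","Leu-61","Leu-63","Trp-64"))
#> [1] 66.66667   # reported as 67%

# 3. Synthetic adsorption scenario, analysed end to end
run <- generate_trajectory(scenario_spec(seed = 42), sheet)
top <- run$traj$topology
ncs <- native_contacts(run$reference)        # 105 native pairs
q_fraction(run$reference$frame, run$reference$topology, ncs)
#> [1] 1
run$truth$anchoring$helix                    # helix anchoring order
#> [1] 2 1 3
tail(run$truth$q, 1)                         # native contacts retained at 20 ns
#> [1] 0.2761905
run$truth$fss_counts[c(1, 101), ]            # shell waters: bulk vs adsorbed
#>      64 55
#> [1,] 18 18
#> [2,]  6 12
```

The numbers read: the bundle starts fully folded (Q = 1), helix 2 anchors
first, and by the end of the 20 ns scenario only ~28% of native contacts
survive while the tracked aromatic residue has lost 12 of its 18 shell
waters (nanoscale drying) and the basic residue only 6.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_build_sheet.R` ... `07_report.R`), each a thin narrative driver over
the package functions, writing tables under `results/`.

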
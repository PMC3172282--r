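# pocketdyn

Trajectory analysis of how a JmjC-domain histone demethylase reads the
methylation state of a lysine side chain. The enzyme (an Fe(II)/
2-oxoglutarate oxygenase of the JMJD2 family) is active on tri- and
dimethylated H3K9 but barely on the monomethylated form, and a large part
of that discrimination is geometric: the methylammonium head sits in an
oxygen-lined pocket, rotates about the lysine CE–NZ bond among three
rotamer wells, and only the *trans* well points a methyl group at the
catalytic Fe(II). `pocketdyn` implements the analyses that quantify this
picture on molecular-dynamics trajectories, plus a kinetic Monte Carlo
generator of synthetic rotamer-jump trajectories so every stage can be
exercised and tested without running MD.

## What it computes

For a structure (PDB) plus trajectory (multi-model PDB or XYZ), or a
generated synthetic system:

- **Torsion rotamer analysis.** The CD-CE-NZ-CZx dihedral per frame,
  discretized into the three 120°-wide states — g+ (centred +60°), g−
  (−60°) and t (180°). Populations and consecutive-frame transition
  counts are Boltzmann-inverted into relative state free energies,
  ΔG_i = −kT ln(p_i / p_max), and per-transition barrier estimates,
  ΔE‡(i→j) = −kT ln(n(i→j) / n_i), with k = 1.987×10⁻³ kcal/(mol·K).
  A transition never observed reports an infinite barrier. Differences
  between barriers are the supported output; absolute values carry the
  unknown attempt-frequency offset.
- **Sphere occupancy.** The fraction of frames each methyl carbon lies
  within a radius (default 4.7 Å, sweep 4.6–4.8 Å) of Fe(II) — reported
  per atom, as the union ("any methyl inside") and as the per-atom sum,
  which coincide only in the single-occupancy regime.
- **Distance statistics.** NZ–pocket-oxygen and Fe–water mean ± standard
  deviation, and the positional fluctuation of any atom (e.g. Fe).
- **Hydrogen-bond census.** Geometric detection with donor–acceptor
  distance R and D–H–A angle θ: strict criteria R < 3.0 Å, 120° < θ ≤ 180°,
  or the loosened C–H···O screen (R < 3.4 Å) with carbon donors admitted.
  Occupancies over an analysis window, mean distance, mean deviation from
  linearity, and classification into main-chain/side-chain and
  interface/intra-substrate/intra-enzyme bonds.
- **Steric clash scan.** Rigid rotation of the methylammonium head about
  CE→NZ in −120° steps with the pocket held fixed; a pair clashes when
  d < r_i + r_j − 0.4 Å (van der Waals radii from a packaged element
  table, per-atom overrides supported).
- **Interface energy decomposition.** Per-residue trajectory-averaged
  Lennard-Jones + Coulomb interaction between enzyme and substrate
  selections (Lorentz–Berthelot combining, Coulomb constant
  332.0636 kcal·Å/(mol·e²), internal dielectric 4 by default). This is the
  gas-phase molecular-mechanics core of an interface decomposition;
  continuum solvation and entropy terms are out of scope.
- **Backbone RMSD series** via Kabsch superposition, for stability traces.

The synthetic generator (`simulate_preset`, `pocket_spec`,
`rotamer_kinetics`) emulates the statistical structure these analyses
assume: a Markov jump process among the three wells (with forbidden
transitions expressible as infinite barriers, e.g. the g−↔g+ hop of the
dimethyl case), an idealized oxygen cage with symmetric and restricted
variants, Fe-coordinating waters, and controllable torsional wobble and
Cartesian jitter. The hidden state sequence is returned so recovery can
be tested against ground truth.

## Worked example

```r
library(pocketdyn)

sim <- simulate_preset("me3", n_frames = 20000, seed = 42)
pk  <- sim$pocket
quad <- c(pk$head_atoms$CD, pk$head_atoms$CE, pk$head_atoms$NZ,
          pk$head_atoms$CZ[1])

tor <- dihedral_series(sim$trajectory, quad, label = "CZ1")
st  <- state_statistics(assign_states(tor), temperature = 310)
st
#> state_stats over 20000 frames at 310 K
#>   populations:     g+=0.3233  g-=0.3622  t=0.3145
#>   energies (kcal/mol): g+=0.070  g-=-0.000  t=0.087
#>   transition counts:
#>     to
#> from  g+  g-   t
#>   g+   0 143 121
#>   g- 129   0 147
#>   t  134 133   0
#>   barrier estimates (kcal/mol, attempt-frequency offset included):
#>       g+    g-     t
#> g+    NA 2.348 2.451
#> g- 2.481    NA 2.401
#> t  2.371 2.375    NA

occupancy_frequency(sim$trajectory, pk$fe_atom, pk$head_atoms$CZ,
                    radius = 4.7)
#> occupancy within 4.70 A over 20000 frames
#>   B/M3L9/CZ1         31.4%
#>   B/M3L9/CZ2         32.3%
#>   B/M3L9/CZ3         36.2%
#>   union 99.9%  sum 99.9%
```

The trimethyl preset visits the three wells nearly uniformly (relative
energies within 0.1 kcal/mol of zero) and the six barrier estimates agree
to within sampling error, the free-rotation signature; because the three
methyls are 120° apart, some methyl is essentially always within 4.7 Å of
Fe(II). Running the same pipeline on the `"me2"` preset gives zero direct
g−↔g+ transitions (infinite barrier estimate), and on `"me1"` a single
methyl whose sphere occupancy equals its *trans* population.

The whole battery runs as one pipeline:

```r
cfg <- run_config(synthetic = list(case = "me3", n_frames = 10000, dt = 1),
                  seed = 7, out_dir = "run_me3")
run_pipeline(cfg)
```

writing `rmsd.csv`, `dihedrals.csv`, `states_populations.csv`,
`states_transitions.csv`, `occupancy.csv`, `distances.csv`, `hbonds.csv`,
`clashes.csv`, `energy.csv`, a `report.json` of headline numbers and a
`manifest.json` (config hash, seed, version, per-stage status). Repeated
runs with the same configuration are byte-identical. A thin command-line
front end is installed under `inst/scripts/pocketdyn-cli.R`
(`simulate`, `run`, single-stage subcommands, `report`); YAML config files
round-trip through `read_config()`.

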
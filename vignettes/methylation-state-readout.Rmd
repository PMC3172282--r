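---
title: "Reading out lysine methylation state from pocket dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading out lysine methylation state from pocket dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketdyn)
```

## The scientific question

JmjC-domain demethylases remove methyl groups from lysines via an
Fe(II)/2-oxoglutarate mechanism that requires a methyl carbon to sit close
to the catalytic iron. The JMJD2 family is efficient on trimethylated and
dimethylated H3K9 but nearly inactive on the monomethylated form.
`pocketdyn` packages the trajectory analyses that make this discrimination
quantitative: the rotameric freedom of the methylammonium head about the
lysine CE–NZ bond, the occupancy of a sphere around Fe(II) by methyl
carbons, the hydrogen-bond network at the enzyme–substrate interface and
inside the substrate, steric clashes under rigid rotation of the head, and
a per-residue nonbonded decomposition of the interface energy.

## Rotamer model and Boltzmann inversion

The torsion of interest is CD-CE-NZ-CZx — the rotation about CE–NZ, read
for each methyl carbon. Angles live on (−180°, +180°], +180° canonical for
*trans*. The circle is discretized into three 120° arcs:

* (0°, 120°] → g+ (well centre +60°)
* (−120°, 0°] → g− (centre −60°)
* (120°, 180°] ∪ (−180°, −120°] → t (centre 180°)

Boundary values belong to the arc whose half-open upper edge they hit, so
exactly 120° is g+ and exactly 0° is g−. The *trans* state is the
catalytically productive one: in the idealized pocket the Fe(II) site lies
along the trans-methyl direction, so whichever methyl is in t points at
the iron.

From a labelled series, `state_statistics()` computes populations
$p_i = n_i/N$, relative free energies
$\Delta G_i = -kT\,\ln(p_i/p_{\max})$ (minimum pinned at zero,
$k = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹, default $T = 310$ K so
$kT = 0.616$ kcal/mol), transition counts on consecutive frames at native
frame resolution, and barrier estimates from per-opportunity transition
probabilities,
$\Delta E^{\ddagger}(i\to j) = -kT\,\ln\!\big(n(i\to j)/n_i\big)$.

Two caveats are deliberate. First, transitions are counted at native
resolution: decimating frames for display is presentation, not analysis,
and must not change statistics. Second, the barrier estimator contains the
unknown attempt frequency as an additive offset $-kT\ln\kappa$, so only
*differences* between barriers (and the infinite/finite distinction) are
supported conclusions. A transition never observed from a visited state
reports $+\infty$; an unvisited origin state reports `NA`. All state
operations accept an analysis window, because equilibration spans are
routinely dropped (the classic pattern is keeping the last ~14 ns of an
18 ns run).

## What the synthetic generator emulates

Real MD trajectories of this system are not distributed with the package,
so the generator produces trajectories with the statistical structure the
analyses assume; it is first-class, tested code.

**Kinetics.** A discrete-time Markov chain over (g+, g−, t) with per-frame
transition probability $p(i\to j) = \kappa\,e^{-B_{ij}/kT}$. The attempt
prefactor defaults to $\kappa = 0.1$ per frame — small enough that
per-step exit probabilities stay below 1 for any non-negative barrier, and
documented because it is exactly the offset the barrier estimator cannot
see. Barriers may be given directly (any ordered matrix obeying
$B_{ij} \ge \max(0, E_j - E_i)$) or derived from symmetric
transition-state energies, $B_{ij} = TS_{ij} - E_i$, in which case
detailed balance holds and the stationary distribution is Boltzmann in the
state energies — this is the analytic oracle the recovery tests use.
`Inf` encodes a forbidden transition, needed for the dimethyl regime where
the direct g−↔g+ hop never occurs. Presets: `me3` has equal state energies
and equal 1.0 kcal/mol barriers (free rotation; chosen low enough that a
$10^5$-frame run mixes far past its integrated autocorrelation time, so
population estimates are tight); `me2` forbids g−↔g+ and raises the g+/t
barrier; `me1` makes g− distinctly lowest and the g+→t passage rare.

**Geometry.** The head is built at ideal tetrahedral geometry: CE–NZ and
N–C bonds 1.49 Å, CE-NZ-CZ angles 109.5°, successive methyls offset 120°
in torsion; methyls (plus optional hydrogens) form a rigid group rotated
about CE→NZ each frame. The pocket is an idealized cage of the six
oxygen roles (Gly170:O, Tyr175:OH, Tyr177:OH, Ser288:OG, Asn290:OD1,
Glu190:OE1/OE2), all 4.2 Å from NZ in the symmetric default. The
restricted variant emulating the lower methylation states pulls Asn290:OD1
and Gly170:O to 3.1 Å near the trans torsion, which is what makes rotated
poses clash. Fe sits 5.6 Å from NZ along the trans-methyl direction
(trans methyl ≈ 4.1 Å from Fe, gauche methyls ≈ 6.3 Å, so the 4.7 Å
sphere cleanly separates them); waters, present for me1/me2, coordinate Fe
at 2.15 Å with the first one between Fe and the head. Per-frame noise is a
within-well torsional wobble (σ = 15°, comfortably inside the 60° distance
to the bin edges) plus isotropic Cartesian jitter (σ = 0.05 Å) on every
atom. Each simulation embeds its seed in the structure title and can be
written with a JSON sidecar holding the hidden state sequence and all
parameters.

**What it does not emulate.** No force-field dynamics: no correlated
motions, no water exchange, no side-chain relaxation, no barrier
anharmonicity. Passing tests therefore demonstrate that the *estimators*
recover known ground truth under the assumed statistical structure — not
that real trajectories satisfy those assumptions. Quantities that depend
on the real ensemble (e.g. the measured sphere-occupancy percentages of a
real me3 trajectory) are not reproduced by the synthetic presets and are
not claimed.

## Geometric criteria and their edge cases

**Hydrogen bonds.** R is the donor–acceptor heavy-atom distance (the
reading consistent with 3.0/3.4 Å magnitudes; the hydrogen–acceptor
alternative is exposed as an option), θ the D–H–A angle; satisfaction is
R < r_max and θ_min < θ ≤ θ_max, strict default 3.0 Å/120°, C–H···O screen
3.4 Å/120°. Hydrogens pair with their donor heavy atom by name within the
residue (H→N, HZ1→NZ, HH11→NH1, water H1/H2→O; when a name stem is
ambiguous, nitrogen/oxygen candidates win over carbon in strict mode)
because no bond graph is read from PDB input. Occupancy divides satisfied
frames by the window length; mean distance and mean deviation from
linearity (180° − θ) average over satisfied frames only. Waters classify
as side chain; the main-chain atom set is {N, CA, C, O, OXT, H, HA,
H1/H2/H3}. Structures without hydrogens raise an explicit error from the
census (the pipeline records an empty table instead), since geometric
criteria cannot apply.

**Clashes.** A head/environment pair clashes when
d < r_i + r_j − tolerance, tolerance 0.4 Å, radii from the element table
(H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, Fe 1.30 Å) unless a per-atom
radius was assigned via the parameter sidecar. The CD/CE/NZ stem is
excluded from the environment (1-2/1-3 neighbours of the rotated group).
The scan default is the −120° ladder (0°, −120°, −240°): for a symmetric
trimethyl head these poses are equivalent, so equal clash counts across
the scan are the no-new-overlap signature, while the restricted pocket
produces clashes only in rotated poses. Side chains are held fixed —
relaxation is explicitly not modelled, so clash counts are upper bounds on
what an energy-minimized pose would show.

**Nonbonded decomposition.** Coulomb $= 332.0636\,q_iq_j/(\varepsilon r)$
with internal dielectric 4 (the conventional value for buried protein
interfaces), Lennard-Jones with Lorentz–Berthelot combining; only
enzyme↔substrate pairs are summed, so intramolecular exclusions never
arise, and both sides' per-residue rows must sum to the same interface
total (conservation is asserted to 10⁻⁹ kcal/mol). No distance cutoff by
default at desk scale. Because the continuum-solvation screening term is
out of scope, per-residue *rankings* for charged residues may differ from
a solvated decomposition; outputs are gas-phase MM values and labelled as
such.

## Numerical choices

* Angles wrap through the modulo map into (−180°, 180°]; ties at bin edges
  go to the half-open upper edge. Degenerate dihedrals (coincident or
  collinear points) raise domain errors rather than returning NaN; series
  propagation names the offending frame.
* Superposition uses the Kabsch construction via singular value
  decomposition with the determinant correction, so reflections are never
  returned; an identity fit returns the identity transform to machine
  precision.
* Sphere occupancy counts strict inequality d < r, so an atom resting
  exactly on the shell counts outside.
* Positional fluctuation is the RMS deviation from the trajectory-mean
  position without superposition; for isotropic Gaussian jitter of width
  σ per coordinate its expectation is √3·σ.
* Distance statistics report the population (not sample) standard
  deviation.
* The stationary distribution of a kinetics object is computed from the
  transition matrix's unit eigenvector, and generator runs start from it,
  so empirical populations are unbiased from frame one.

## Design decisions that were genuinely open

* **Discrete-time jumps rather than continuous-time kinetic Monte Carlo:**
  the analyses consume evenly spaced frames, so a per-frame chain is
  sufficient and keeps the attempt prefactor explicit.
* **Union vs sum in sphere occupancy:** an additive per-methyl total only
  equals the "any methyl inside" frequency under single occupancy, so both
  are always reported side by side rather than guessing which a summary
  table means.
* **Fixture naming:** methylated-lysine residues are M1L/M2L/M3L with
  methyl carbons CZ1..CZ3, amine protons HN1/HN2 and methyl hydrogens
  HZ11..HZ33 — chosen so the name-based donor pairing is unambiguous,
  since deposited structures carry no single convention.
* **Config files are YAML** (flat, documented keys, CLI flags override),
  round-tripping losslessly; the manifest records an MD5 hash of the
  canonical JSON form of the configuration, so the hash changes exactly
  when a field changes.
* **Trajectory dialects are text only** (multi-model PDB, XYZ): binary
  formats belong to MD engines, and desk-scale synthetic data does not
  need them.

## Problem sizes and verification

The test suite verifies each estimator against an independent oracle:
dihedrals against a Rodrigues-rotation construction (10³ random quads,
10⁻⁶ degree agreement), superposition against a rotation-space search and
bio3d, censuses and decompositions against plain loop oracles,
state/barrier machinery against the generator's hidden sequence and the
analytic stationary distribution. Statistical recoveries run at 10⁵
frames (populations within 0.02 of target, pooled barrier-difference
errors under 0.1 kcal/mol across a 1.5/2.0/2.5 kcal/mol ladder over three
seeds); the end-to-end pipeline check uses a 10⁴-frame trimethyl run and
asserts byte-identical outputs across repeated runs. These sizes keep the
full suite under a minute on one CPU while leaving the statistical
assertions several standard errors of headroom.

## Known limitations

* Barrier estimates are per-frame transition probabilities inverted
  through a fixed temperature; they are not free-energy profiles, and no
  Markov-state-model lumping beyond the three fixed states is attempted.
* The hydrogen-bond census requires explicit hydrogens and name-based
  pairing; exotic hydrogen naming schemes may need the parameter sidecar
  or renaming.
* No periodic-boundary unwrapping: inputs are assumed whole molecules.
* The energy module stops at gas-phase MM; solvation, entropy and binding
  free energies are out of scope by design.
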
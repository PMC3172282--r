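Package: pocketdyn
Title: Rotamer, Contact and Interface Analysis of Methyllysine
    Recognition Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for studying how an
    Fe(II)/2-oxoglutarate histone demethylase discriminates mono-, di-
    and trimethylated lysine substrates. Measures the torsion about the
    lysine CE-NZ bond, discretizes it into the three rotamer states
    (gauche+, gauche-, trans), Boltzmann-inverts state populations and
    transition frequencies into relative free energies and barrier
    estimates, quantifies methyl-carbon occupancy of a sphere around
    the catalytic Fe(II), detects hydrogen bonds under strict and loose
    (C-H...O) geometric criteria with occupancies and main-chain/
    side-chain classification, scans rigid -120 degree rotations of the
    methylammonium head for steric clashes, and decomposes the
    enzyme-substrate nonbonded interface energy (Lennard-Jones plus
    Coulomb) per residue. Includes a kinetic Monte Carlo generator of
    synthetic rotamer-jump trajectories in an idealized oxygen-lined
    binding pocket so every stage is testable without molecular
    dynamics input, plus multi-model PDB and XYZ readers and writers
    and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
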
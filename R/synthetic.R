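## Synthetic rotamer-jump trajectories in an idealized oxygen-lined pocket.
## These generators emulate the statistical structure the analyses assume:
## a methyllysine head hopping among three torsion wells by a discrete-time
## Markov chain, embedded in a rigid pocket with an Fe site, labelled pocket
## oxygens, optional Fe-coordinating waters, and controllable noise.

.rot_states <- c("g+", "g-", "t")
.state_centres <- c("g+" = 60, "g-" = -60, "t" = 180)

#' Rotamer-jump kinetics
#'
#' Defines the three-state discrete-time Markov model of the torsion about
#' CE-NZ. Per-step transition probability is `p(i->j) =
#' kappa * exp(-barrier(i->j) / kT)`. Barriers may be given directly as an
#' ordered 3x3 matrix (rows = from, cols = to, states g+, g-, t) or derived
#' from symmetric transition-state energies `ts` (named `"g+_g-"`,
#' `"g-_t"`, `"g+_t"`, kcal/mol above the global minimum), in which case
#' `barrier(i->j) = ts(i,j) - E(i)` and detailed balance holds, so the
#' stationary state populations are Boltzmann in `state_energies`.
#' `Inf` encodes a forbidden transition.
#'
#' @param state_energies Named numeric, kcal/mol relative to the minimum,
#'   names `g+`, `g-`, `t`.
#' @param ts Named symmetric transition-state energies (see above), or `NULL`
#'   when `barriers` is given.
#' @param barriers Optional ordered 3x3 barrier matrix, kcal/mol.
#' @param temperature Kelvin.
#' @param kappa Attempt prefactor per frame.
#' @return Object of class `rotamer_kinetics` with the transition matrix `P`.
#' @export
rotamer_kinetics <- function(state_energies = c("g+" = 0, "g-" = 0, "t" = 0),
                             ts = c("g+_g-" = 1, "g-_t" = 1, "g+_t" = 1),
                             barriers = NULL, temperature = 310,
                             kappa = 0.1) {
  E <- state_energies[.rot_states]
  if (anyNA(E)) stop("state_energies must name g+, g-, t")
  E <- E - min(E)
  if (is.null(barriers)) {
    pair_key <- function(i, j) {
      k <- paste0(i, "_", j)
      if (!k %in% names(ts)) k <- paste0(j, "_", i)
      k
    }
    barriers <- matrix(NA_real_, 3, 3, dimnames = list(.rot_states, .rot_states))
    for (i in .rot_states) for (j in .rot_states) if (i != j)
      barriers[i, j] <- ts[[pair_key(i, j)]] - E[[i]]
  }
  dimnames(barriers) <- list(.rot_states, .rot_states)
  for (i in .rot_states) for (j in .rot_states) if (i != j) {
    b <- barriers[i, j]
    if (is.na(b)) stop("missing barrier ", i, "->", j)
    if (b < max(0, E[[j]] - E[[i]]) - 1e-9)
      stop("barrier ", i, "->", j, " (", b,
           ") below the uphill energy difference")
  }
  kT <- .kB * temperature
  P <- matrix(0, 3, 3, dimnames = list(.rot_states, .rot_states))
  for (i in .rot_states) for (j in .rot_states) if (i != j)
    P[i, j] <- kappa * exp(-barriers[i, j] / kT)
  if (any(rowSums(P) > 1))
    stop("per-step total transition probability exceeds 1; ",
         "lower kappa or raise barriers")
  diag(P) <- 1 - rowSums(P)
  structure(list(state_energies = E, barriers = barriers, P = P,
                 temperature = temperature, kappa = kappa),
            class = "rotamer_kinetics")
}

#' Analytic stationary distribution of the jump chain
#' @param kinetics A [rotamer_kinetics()].
#' @return Named probability vector over (g+, g-, t).
#' @export
stationary_distribution <- function(kinetics) {
  ev <- eigen(t(kinetics$P))
  k <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, k]))
  stats::setNames(v / sum(v), .rot_states)
}

#' @export
print.rotamer_kinetics <- function(x, ...) {
  cat("rotamer_kinetics: T =", x$temperature, "K, kappa =", x$kappa, "\n")
  cat("  state energies (kcal/mol):",
      paste(sprintf("%s=%.3f", .rot_states, x$state_energies), collapse = " "),
      "\n  barriers (kcal/mol):\n")
  print(round(x$barriers, 3))
  invisible(x)
}

#' Noise model for the generator
#' @param jitter_sigma Isotropic Gaussian Cartesian jitter, Angstrom
#'   per atom per frame.
#' @param dihedral_sigma Within-well torsional wobble, degrees.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(jitter_sigma = 0.05, dihedral_sigma = 15) {
  stopifnot(jitter_sigma >= 0, dihedral_sigma >= 0)
  structure(list(jitter_sigma = jitter_sigma,
                 dihedral_sigma = dihedral_sigma), class = "noise_model")
}

## Place atom D from A, B, C with bond |C-D|, angle B-C-D and dihedral
## A-B-C-D (degrees). Construction matches the sign convention of dihedral().
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Idealized methylammonium binding pocket
#'
#' Builds the rigid fixture geometry: lysine CD-CE-NZ stem, one to three
#' methyl carbons at ideal tetrahedral geometry about NZ (N-C 1.49 Angstrom,
#' CE-NZ-CZ 109.5 degrees, successive methyls offset 120 degrees in torsion),
#' an Fe site 5.6 Angstrom from NZ along the trans-methyl direction (so the
#' trans state aligns a methyl with Fe), and the six pocket-oxygen roles
#' (Gly170:O, Tyr175:OH, Tyr177:OH, Ser288:OG, Asn290:OD1, Glu190:OE1/OE2).
#' The symmetric default places all oxygens 4.2 Angstrom from NZ; the
#' asymmetric variant pulls Asn290:OD1 and Gly170:O to 3.1 Angstrom near the
#' trans torsion, emulating the restricted environment seen for the lower
#' methylation states. Waters sit 2.15 Angstrom from Fe, the first between
#' Fe and the head.
#'
#' In the base pose the CZ1 torsion (CD-CE-NZ-CZ1) is 0 degrees; use
#' [pocket_pose()] for a representative pose in a chosen well. The head
#' (methyl carbons plus any head hydrogens) is rigid about the CE-NZ axis.
#'
#' @param methyl_count 1, 2 or 3.
#' @param symmetric Logical; `FALSE` selects the pulled-oxygen variant.
#' @param waters Logical; default `TRUE` for methyl_count < 3 (the
#'   trimethyl pocket has no room for them).
#' @param hydrogens Logical; add methyl hydrogens (`HZ11` ... on CZ1, etc.)
#'   and amine protons (`HN1`, `HN2`) at the free tetrahedral slots, for
#'   hydrogen-bond census fixtures.
#' @param cage_radius NZ-O distance of the symmetric cage, Angstrom.
#' @param pulled_radius NZ-O distance of the pulled oxygens, Angstrom.
#' @param fe_distance NZ-Fe distance, Angstrom.
#' @return Object of class `pocket_spec`: a [structure_model()] plus base
#'   coordinates and bookkeeping indices.
#' @export
pocket_spec <- function(methyl_count = 3, symmetric = methyl_count == 3,
                        waters = methyl_count < 3, hydrogens = FALSE,
                        cage_radius = 4.2, pulled_radius = 3.1,
                        fe_distance = 5.6) {
  stopifnot(methyl_count %in% 1:3)
  ce <- c(0, 0, -1.49)
  nz <- c(0, 0, 0)
  cd <- ce + 1.53 * c(sin(111 * pi / 180), 0, cos(111 * pi / 180))
  place <- function(r, angle, torsion) .place_atom(cd, ce, nz, r, angle, torsion)
  ox <- list(
    `Gly170:O`   = if (symmetric) place(cage_radius, 90, 0)
                   else place(pulled_radius, 90, 165),
    `Asn290:OD1` = if (symmetric) place(cage_radius, 90, 120)
                   else place(pulled_radius, 90, 195),
    `Ser288:OG`  = place(cage_radius, 90, 240),
    `Tyr175:OH`  = place(cage_radius, 60, 60),
    `Tyr177:OH`  = place(cage_radius, 60, 180),
    `Glu190:OE1` = place(cage_radius, 60, 300),
    `Glu190:OE2` = place(cage_radius, 45, 300))
  fe <- place(fe_distance, 109.5, 180)
  u_fe <- (fe - nz) / sqrt(sum((fe - nz)^2))
  wat <- NULL
  if (waters) {
    perp <- .cross3(u_fe, c(1, 0, 0)); perp <- perp / sqrt(sum(perp^2))
    wat <- list(Wat1 = fe - 2.15 * u_fe,
                Wat2 = fe + 2.15 * perp,
                Wat3 = fe + 2.15 * .cross3(u_fe, perp))
  }
  res_of <- function(lbl) as.integer(sub("^[A-Za-z]+(\\d+):.*$", "\\1", lbl))
  atoms <- data.frame(
    serial = integer(0), name = character(0), element = character(0),
    residue_name = character(0), residue_number = integer(0),
    chain_id = character(0), stringsAsFactors = FALSE)
  coords <- NULL
  add <- function(name, element, resname, resno, chain, xyz) {
    atoms <<- rbind(atoms, data.frame(
      serial = nrow(atoms) + 1L, name = name, element = element,
      residue_name = resname, residue_number = resno, chain_id = chain,
      stringsAsFactors = FALSE))
    coords <<- rbind(coords, xyz)
  }
  for (lbl in names(ox)) {
    res3 <- toupper(substr(lbl, 1, 3))
    add(sub("^.*:", "", lbl), "O", res3, res_of(lbl), "A", ox[[lbl]])
  }
  add("FE", "Fe", "FE2", 400, "A", fe)
  if (waters)
    for (w in seq_along(wat))
      add("O", "O", "HOH", 500L + w, "W", wat[[w]])
  resname <- c("M1L", "M2L", "M3L")[methyl_count]
  add("CD", "C", resname, 9, "B", cd)
  add("CE", "C", resname, 9, "B", ce)
  add("NZ", "N", resname, 9, "B", nz)
  cz_pos <- list()
  for (k in seq_len(methyl_count)) {
    cz_pos[[k]] <- place(1.49, 109.5, (k - 1) * 120)
    add(paste0("CZ", k), "C", resname, 9, "B", cz_pos[[k]])
  }
  if (hydrogens) {
    for (k in seq_len(methyl_count))
      for (m in 1:3)
        add(paste0("HZ", k, m), "H", resname, 9, "B",
            .place_atom(ce, nz, cz_pos[[k]], 1.09, 109.5, 60 + (m - 1) * 120))
    free <- setdiff(1:3, seq_len(methyl_count))
    for (m in seq_along(free))
      add(paste0("HN", m), "H", resname, 9, "B",
          place(1.03, 109.5, (free[m] - 1) * 120))
  }
  sm <- structure_model(atoms, title = sprintf("synthetic me%d pocket",
                                               methyl_count))
  sm$atoms$charge <- .pocket_default_charges(sm$atoms)
  sm$atoms$lj_sigma <- c(H = 1.00, C = 3.40, N = 3.25, O = 3.00,
                         Fe = 2.30)[sm$atoms$element]
  sm$atoms$lj_epsilon <- c(H = 0.02, C = 0.09, N = 0.17, O = 0.21,
                           Fe = 0.01)[sm$atoms$element]
  head_rot <- which(sm$atoms$chain_id == "B" &
                    !sm$atoms$name %in% c("CD", "CE", "NZ"))
  structure(list(structure = sm, base_coords = unname(coords),
                 methyl_count = methyl_count, symmetric = symmetric,
                 head_atoms = list(
                   CD = which(sm$atoms$name == "CD"),
                   CE = which(sm$atoms$name == "CE"),
                   NZ = which(sm$atoms$name == "NZ"),
                   CZ = which(grepl("^CZ", sm$atoms$name)),
                   rotating = head_rot),
                 fe_atom = which(sm$atoms$name == "FE"),
                 water_atoms = which(sm$atoms$residue_name == "HOH")),
            class = "pocket_spec")
}

#' Representative pocket pose at a chosen head torsion
#'
#' Rotates the rigid head so the CD-CE-NZ-CZ1 torsion equals `torsion`.
#'
#' @param pocket A [pocket_spec()].
#' @param torsion Target CZ1 torsion, degrees.
#' @return `n_atoms x 3` coordinate matrix.
#' @export
pocket_pose <- function(pocket, torsion) {
  h <- pocket$head_atoms
  rotate_group(pocket$base_coords, h$rotating, h$CE, h$NZ, torsion)
}

## Plausible fixture charges (elementary units): cationic head, anionic
## carboxylate, polar oxygens, Fe(II).
.pocket_default_charges <- function(atoms) {
  ch <- rep(0, nrow(atoms))
  ch[atoms$name == "FE"] <- 2.0
  ch[atoms$name %in% c("OE1", "OE2")] <- -0.80
  ch[atoms$name %in% c("O", "OG", "OH", "OD1") & atoms$chain_id == "A"] <- -0.50
  ch[atoms$residue_name == "HOH"] <- -0.40
  ch[atoms$name == "NZ"] <- 0.30
  ch[grepl("^CZ", atoms$name)] <- 0.25
  ch[atoms$name == "CE"] <- 0.10
  ch
}

#' @export
print.pocket_spec <- function(x, ...) {
  cat("pocket_spec: me", x$methyl_count,
      if (x$symmetric) ", symmetric cage" else ", asymmetric (pulled) cage",
      ", ", .n_atoms(x$structure), " atoms",
      if (length(x$water_atoms)) sprintf(", %d waters",
                                         length(x$water_atoms)),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a rotamer-jump trajectory
#'
#' Draws a discrete-time Markov state sequence from `kinetics` (initial
#' state from the analytic stationary distribution), places the methyl
#' carbons at the state's torsion centre (g+ = +60, g- = -60, t = 180
#' degrees) plus Gaussian torsional wobble, then adds isotropic Cartesian
#' jitter to every atom. All pocket atoms are static apart from jitter.
#' The hidden true state sequence is returned for recovery tests.
#'
#' @param kinetics A [rotamer_kinetics()].
#' @param pocket A [pocket_spec()].
#' @param noise A [noise_model()].
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame interval, ps.
#' @param seed Integer seed; the same seed reproduces the coordinate stream
#'   bitwise.
#' @return Object of class `rotamer_sim`: list with `trajectory`, `states`
#'   (character vector of hidden states), `torsions` (pre-jitter CZ1 torsion
#'   per frame, degrees), and the generation parameters.
#' @export
simulate_rotamer_trajectory <- function(kinetics, pocket,
                                        noise = noise_model(),
                                        n_frames, dt = 1, seed = 1) {
  stopifnot(n_frames >= 1)
  set.seed(seed)
  P <- kinetics$P
  pi0 <- stationary_distribution(kinetics)
  states <- integer(n_frames)
  states[1] <- sample.int(3, 1, prob = pi0)
  if (n_frames > 1) {
    u <- stats::runif(n_frames - 1)
    cum <- t(apply(P, 1, cumsum))
    for (f in 2:n_frames)
      states[f] <- findInterval(u[f - 1], cum[states[f - 1], ]) + 1L
  }
  centres <- .state_centres[.rot_states[states]]
  wobble <- stats::rnorm(n_frames, 0, noise$dihedral_sigma)
  torsions <- .wrap180(centres + wobble)

  sm <- pocket$structure
  na <- .n_atoms(sm)
  coords <- array(rep(as.numeric(pocket$base_coords), each = n_frames),
                  c(n_frames, na, 3))
  h <- pocket$head_atoms
  ce <- pocket$base_coords[h$CE, ]
  nz <- pocket$base_coords[h$NZ, ]
  u <- (nz - ce) / sqrt(sum((nz - ce)^2))
  ph <- torsions * pi / 180
  for (idx in h$rotating) {
    v <- pocket$base_coords[idx, ] - nz
    vpar <- sum(v * u) * u
    vperp <- v - vpar
    w <- .cross3(u, vperp)
    coords[, idx, ] <- outer(rep(1, n_frames), nz + vpar) +
      outer(cos(ph), vperp) + outer(sin(ph), w)
  }
  if (noise$jitter_sigma > 0)
    coords <- coords + stats::rnorm(length(coords), 0, noise$jitter_sigma)
  sm$title <- sprintf("%s | rotamer-jump sim seed=%d n=%d dt=%g",
                      sm$title, seed, n_frames, dt)
  traj <- trajectory(sm, coords, dt = dt)
  structure(list(trajectory = traj, states = .rot_states[states],
                 torsions = torsions, kinetics = kinetics, pocket = pocket,
                 noise = noise, seed = seed),
            class = "rotamer_sim")
}

#' @export
print.rotamer_sim <- function(x, ...) {
  tb <- table(factor(x$states, levels = .rot_states))
  cat("rotamer_sim: me", x$pocket$methyl_count, ", ",
      length(x$states), " frames, seed ", x$seed, "\n  state fractions: ",
      paste(sprintf("%s=%.3f", names(tb), tb / length(x$states)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Preset kinetics for the three methylation states
#'
#' `me3`: equal state energies and equal 1.0 kcal/mol barriers (free
#' rotation, all three wells equally visited). `me2`: g+ <-> g- forbidden
#' (infinite barrier, no circular motion) and a higher g+/t barrier than
#' its me3 conjugate. `me1`: g- well distinctly lowest and the g+ -> t
#' transition made energetically demanding and rare.
#'
#' @param case `"me1"`, `"me2"` or `"me3"`.
#' @param temperature Kelvin.
#' @param kappa Attempt prefactor per frame.
#' @return A [rotamer_kinetics()].
#' @export
kinetics_preset <- function(case = c("me3", "me2", "me1"), temperature = 310,
                            kappa = 0.1) {
  case <- match.arg(case)
  switch(case,
    me3 = rotamer_kinetics(c("g+" = 0, "g-" = 0, "t" = 0),
                           ts = c("g+_g-" = 1, "g-_t" = 1, "g+_t" = 1),
                           temperature = temperature, kappa = kappa),
    me2 = rotamer_kinetics(c("g+" = 0.6, "g-" = 0, "t" = 0.3),
                           ts = c("g+_g-" = Inf, "g-_t" = 1.2, "g+_t" = 2.2),
                           temperature = temperature, kappa = kappa),
    me1 = rotamer_kinetics(c("g+" = 0.6, "g-" = 0, "t" = 1.0),
                           ts = c("g+_g-" = 1.5, "g-_t" = 2.0, "g+_t" = 3.2),
                           temperature = temperature, kappa = kappa))
}

#' One-call preset simulation
#' @param case `"me1"`, `"me2"` or `"me3"`.
#' @param n_frames Frames to simulate.
#' @param dt Frame interval, ps.
#' @param seed Integer seed.
#' @param noise A [noise_model()].
#' @return A `rotamer_sim` (see [simulate_rotamer_trajectory()]).
#' @export
simulate_preset <- function(case = c("me3", "me2", "me1"), n_frames = 10000,
                            dt = 1, seed = 1, noise = noise_model()) {
  case <- match.arg(case)
  me <- as.integer(substr(case, 3, 3))
  simulate_rotamer_trajectory(kinetics_preset(case), pocket_spec(me),
                              noise = noise, n_frames = n_frames, dt = dt,
                              seed = seed)
}

#' Write a simulation with its JSON sidecar
#'
#' Emits the trajectory (multi-model PDB or XYZ), the structure PDB, and a
#' JSON sidecar holding the hidden state sequence and all generation
#' parameters.
#'
#' @param sim A `rotamer_sim`.
#' @param dir Output directory (created if needed).
#' @param dialect `"xyz"` or `"pdb"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, dialect = c("xyz", "pdb")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj_path <- file.path(dir, paste0("trajectory.", dialect))
  if (dialect == "xyz") write_xyz(sim$trajectory, traj_path)
  else write_pdb(sim$trajectory, traj_path)
  struct_path <- file.path(dir, "structure.pdb")
  write_pdb(sim$trajectory$structure, struct_path,
            coords = frame_coords(sim$trajectory, 1))
  sidecar <- list(
    seed = sim$seed, n_frames = length(sim$states), dt = sim$trajectory$dt,
    methyl_count = sim$pocket$methyl_count,
    temperature = sim$kinetics$temperature, kappa = sim$kinetics$kappa,
    state_energies = as.list(sim$kinetics$state_energies),
    barriers = sim$kinetics$barriers,
    jitter_sigma = sim$noise$jitter_sigma,
    dihedral_sigma = sim$noise$dihedral_sigma,
    states = sim$states)
  side_path <- file.path(dir, "simulation.json")
  jsonlite::write_json(sidecar, side_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(trajectory = traj_path, structure = struct_path,
              sidecar = side_path))
}

#' Constructed hydrogen-bond occupancy fixture
#'
#' A three-atom donor/hydrogen/acceptor trajectory in which exactly
#' `round(fraction * n_frames)` frames satisfy the strict geometric criteria
#' (donor-acceptor distance < 3.0 Angstrom, angle > 120 degrees) and every
#' other frame violates the distance by at least 0.2 Angstrom or the angle
#' by at least 10 degrees. Which frames satisfy is a seeded permutation.
#'
#' @param fraction Target satisfied fraction in `[0, 1]`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param dt Frame interval, ps.
#' @return A [trajectory()] over atoms NH1/HH11 (Arg 8, chain B) and
#'   backbone O (Lys 9, chain B); attribute `"satisfied"` marks the frames
#'   built to satisfy the criteria.
#' @export
make_hbond_fixture <- function(fraction, n_frames, seed = 1, dt = 1) {
  stopifnot(fraction >= 0, fraction <= 1, n_frames >= 1)
  atoms <- data.frame(
    serial = 1:3,
    name = c("NH1", "HH11", "O"),
    element = c("N", "H", "O"),
    residue_name = c("ARG", "ARG", "LYS"),
    residue_number = c(8L, 8L, 9L),
    chain_id = "B", stringsAsFactors = FALSE)
  sm <- structure_model(atoms, title = sprintf(
    "hbond fixture fraction=%g n=%d seed=%d", fraction, n_frames, seed))
  n_sat <- round(fraction * n_frames)
  set.seed(seed)
  sat_frames <- sort(sample.int(n_frames, n_sat))
  d <- c(0, 0, 0); h <- c(1, 0, 0)
  a_good <- c(2.80, 0, 0)                        # R = 2.8, theta = 180
  a_far <- c(3.30, 0, 0)                         # R = 3.3 (>= 0.2 beyond cut)
  u <- c(-cos(105 * pi / 180), sin(105 * pi / 180), 0)
  a_bent <- h + 1.9 * u                          # theta = 105 (>= 10 below cut)
  coords <- array(NA_real_, c(n_frames, 3, 3))
  is_sat <- seq_len(n_frames) %in% sat_frames
  for (f in seq_len(n_frames)) {
    af <- if (is_sat[f]) a_good else if (f %% 2 == 0) a_far else a_bent
    coords[f, , ] <- rbind(d, h, af)
  }
  out <- trajectory(sm, coords, dt = dt)
  attr(out, "satisfied") <- is_sat
  out
}

#' Synthetic peptide backbone fixture
#'
#' A poly-alanine backbone trace (N, CA, C, O per residue) numbered like the
#' histone-tail span the analyses target. With `w_shape = TRUE` the CA trace
#' follows two arcs, giving exactly two interior local minima in its
#' z-profile -- the W-shaped bound conformation the H-bond analysis
#' discusses.
#'
#' @param n_residues At least 4.
#' @param w_shape Logical.
#' @param first_residue Residue number of the first residue (default 7).
#' @return A [structure_model()] with coordinates attached as attribute
#'   `"coords"`.
#' @export
make_peptide_fixture <- function(n_residues = 8, w_shape = FALSE,
                                 first_residue = 7) {
  stopifnot(n_residues >= 4)
  i <- seq_len(n_residues)
  z <- if (w_shape) 1.5 * cos(4 * pi * (i - 1) / (n_residues - 1)) else
    rep(0, n_residues)
  atoms <- NULL; coords <- NULL
  for (r in i) {
    x0 <- 3.8 * r
    block <- data.frame(
      serial = (r - 1) * 4 + 1:4,
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      residue_name = "ALA",
      residue_number = first_residue + r - 1L,
      chain_id = "B", stringsAsFactors = FALSE)
    xyz <- rbind(c(x0 - 1.2, -0.6, z[r]),
                 c(x0, 0, z[r]),
                 c(x0 + 1.3, 0.5, z[r]),
                 c(x0 + 1.3, 1.73, z[r]))
    atoms <- rbind(atoms, block)
    coords <- rbind(coords, xyz)
  }
  sm <- structure_model(atoms, title = sprintf(
    "peptide fixture n=%d%s", n_residues, if (w_shape) " w-shape" else ""))
  attr(sm, "coords") <- unname(coords)
  sm
}
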
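# Fixture builders and independent oracles shared across tests. Oracles
# here are deliberately written without the package's kernels (plain loops,
# direct formulas) so they stay independent of the code paths they check.

kT310 <- 1.987e-3 * 310

# Fixed-column PDB text, built by hand so the parser is tested against an
# independently constructed byte stream.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM  ", alt = " ", element = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%s%5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, nm, alt, resname, chain, resno, x, y, z, element)
}

mini_pdb_text <- function() {
  c(pdb_line(1, "N", "ALA", "B", 7, 1.000, 2.000, 3.000, element = "N"),
    pdb_line(2, "CA", "ALA", "B", 7, 2.500, 2.000, 3.000, element = "C"),
    pdb_line(3, "C", "ALA", "B", 7, 3.200, 3.100, 3.000, element = "C"),
    "END")
}

write_mini_pdb <- function(lines = mini_pdb_text()) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# Independent Rodrigues rotation (right-handed about `axis` through
# `origin`), used as the oracle fixing the dihedral sign convention.
oracle_rotate <- function(p, origin, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  v <- p - origin
  origin + v * cos(th) +
    c(u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1]) * sin(th) +
    u * sum(u * v) * (1 - cos(th))
}

wrap180 <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

# Brute-force minimum RMSD over rigid rotations: many random-start local
# searches over Euler angles after centring, no SVD involved.
oracle_min_rmsd <- function(A, B, n_starts = 40) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rot <- function(ang) {
    c1 <- cos(ang[1]); s1 <- sin(ang[1])
    c2 <- cos(ang[2]); s2 <- sin(ang[2])
    c3 <- cos(ang[3]); s3 <- sin(ang[3])
    matrix(c(c1 * c2, s1 * c2, -s2,
             c1 * s2 * s3 - s1 * c3, s1 * s2 * s3 + c1 * c3, c2 * s3,
             c1 * s2 * c3 + s1 * s3, s1 * s2 * c3 - c1 * s3, c2 * c3), 3, 3)
  }
  obj <- function(ang) sqrt(mean(rowSums((Bc %*% t(rot(ang)) - Ac)^2)))
  best <- Inf
  set.seed(99)
  for (k in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Direct triple-loop hydrogen-bond census (donor-acceptor distance).
oracle_hbond_census <- function(traj, triples, r_max, theta_min) {
  nf <- n_frames(traj)
  nt <- nrow(triples)
  sat <- matrix(FALSE, nf, nt)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (k in seq_len(nt)) {
      d <- xyz[triples$donor[k], ]
      h <- xyz[triples$hydrogen[k], ]
      a <- xyz[triples$acceptor[k], ]
      r <- sqrt(sum((d - a)^2))
      v1 <- d - h; v2 <- a - h
      th <- acos(max(-1, min(1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      sat[f, k] <- r < r_max && th > theta_min && th <= 180
    }
  }
  sat
}

# Exhaustive pairwise clash oracle.
oracle_clashes <- function(coords, head, env, radii, tolerance) {
  hits <- 0
  for (i in head) for (j in env) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d < radii[i] + radii[j] - tolerance) hits <- hits + 1
  }
  hits
}

# A small mixed fixture for the hydrogen-bond census: four residues with
# N-H donors and carbonyl O acceptors, a water, and a methyl with C-H
# donors, jittered over frames.
make_census_fixture <- function(n_frames = 200, seed = 5) {
  atoms <- NULL
  coords0 <- NULL
  add <- function(name, element, resname, resno, chain, xyz) {
    atoms <<- rbind(atoms, data.frame(
      serial = NROW(atoms) + 1L, name = name, element = element,
      residue_name = resname, residue_number = resno, chain_id = chain,
      stringsAsFactors = FALSE))
    coords0 <<- rbind(coords0, xyz)
  }
  set.seed(seed)
  for (r in 1:4) {
    base <- c(3.0 * r, 0, 0)
    add("N", "N", "ALA", r, if (r <= 2) "A" else "B", base)
    add("H", "H", "ALA", r, if (r <= 2) "A" else "B", base + c(0.4, 0.9, 0))
    add("CA", "C", "ALA", r, if (r <= 2) "A" else "B", base + c(1.2, -0.6, 0))
    add("C", "C", "ALA", r, if (r <= 2) "A" else "B", base + c(2.0, 0.2, 0))
    add("O", "O", "ALA", r, if (r <= 2) "A" else "B", base + c(2.2, 1.4, 0))
  }
  add("O", "O", "HOH", 50, "W", c(6.0, 2.6, 0.5))
  add("H1", "H", "HOH", 50, "W", c(5.6, 2.2, 1.2))
  add("H2", "H", "HOH", 50, "W", c(6.6, 3.2, 0.9))
  add("CZ1", "C", "M3L", 9, "B", c(9.0, 2.0, 0))
  for (m in 1:3)
    add(paste0("HZ1", m), "H", "M3L", 9, "B",
        c(9.0, 2.0, 0) + 1.09 * c(cos(2 * pi * m / 3), sin(2 * pi * m / 3),
                                  0.3))
  sm <- structure_model(atoms, title = "census fixture")
  coords <- array(NA_real_, c(n_frames, nrow(atoms), 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- coords0 + matrix(stats::rnorm(length(coords0), 0, 0.25),
                                      ncol = 3)
  trajectory(sm, coords, dt = 1)
}
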
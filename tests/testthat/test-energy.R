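test_that("pair energies reproduce their defining constants and closed forms", {
  p1 <- nonbonded_params(dielectric = 1)
  e <- pair_energy(1, 1, 3.4, 3.4, 0.1, 0.1, r = 1, params = p1)
  expect_equal(e[["coulomb"]], 332.0636, tolerance = 1e-10)
  p4 <- nonbonded_params(dielectric = 4)
  e4 <- pair_energy(1, 1, 3.4, 3.4, 0.1, 0.1, r = 1, params = p4)
  expect_equal(e4[["coulomb"]], 83.0159, tolerance = 1e-6)

  sij <- (3.2 + 3.6) / 2
  at_sigma <- pair_energy(0, 0, 3.2, 3.6, 0.12, 0.3, r = sij)
  expect_equal(at_sigma[["vdw"]], 0, tolerance = 1e-12)
  at_min <- pair_energy(0, 0, 3.2, 3.6, 0.12, 0.3, r = 2^(1 / 6) * sij)
  expect_equal(at_min[["vdw"]], -sqrt(0.12 * 0.3), tolerance = 1e-12)

  # symmetry, 1/eps Coulomb scaling, eps-independent vdw
  a <- pair_energy(0.3, -0.5, 3.1, 3.3, 0.1, 0.2, r = 4.2, params = p4)
  b <- pair_energy(-0.5, 0.3, 3.3, 3.1, 0.2, 0.1, r = 4.2, params = p4)
  expect_equal(a, b)
  a1 <- pair_energy(0.3, -0.5, 3.1, 3.3, 0.1, 0.2, r = 4.2, params = p1)
  expect_equal(a1[["coulomb"]] / 4, a[["coulomb"]], tolerance = 1e-12)
  expect_equal(a1[["vdw"]], a[["vdw"]])

  expect_error(pair_energy(NA, 1, 3, 3, 0.1, 0.1, r = 2), "missing")
})

test_that("a static opposite-charge pair decomposes to the closed form", {
  atoms <- data.frame(
    serial = 1:2, name = c("Q1", "Q2"), element = c("N", "O"),
    residue_name = c("ENZ", "SUB"), residue_number = 1:2,
    chain_id = c("A", "B"), charge = c(1, -1), lj_sigma = c(0, 0),
    lj_epsilon = c(0, 0), stringsAsFactors = FALSE)
  sm <- structure_model(atoms)
  coords <- array(0, c(5, 2, 3))
  coords[, 2, 1] <- 3
  traj <- trajectory(sm, coords)
  dec <- interface_decomposition(traj, enzyme = 1, substrate = 2,
                                 params = nonbonded_params(dielectric = 4))
  expect_equal(nrow(dec), 2)
  expect_equal(dec$coulomb, rep(-332.0636 / 12, 2), tolerance = 1e-9)
  expect_equal(dec$vdw, c(0, 0))
  tot <- interface_totals(dec)
  expect_equal(tot$total[1], tot$total[2], tolerance = 1e-12)

  expect_error(interface_decomposition(traj, 1, integer(0)), "empty")
  expect_error(interface_decomposition(traj, 1:2, 2), "overlap")
})

test_that("decomposition equals the brute-force double loop and conserves totals", {
  # synthetic multi-residue complex: 30 residues of 2 atoms each
  set.seed(27)
  n_res <- 30
  atoms <- data.frame(
    serial = seq_len(2 * n_res),
    name = rep(c("X1", "X2"), n_res),
    element = rep(c("C", "O"), n_res),
    residue_name = rep("RES", 2 * n_res),
    residue_number = rep(seq_len(n_res), each = 2),
    chain_id = rep(c("A", "B"), each = n_res),
    charge = round(runif(2 * n_res, -0.8, 0.8), 3),
    lj_sigma = round(runif(2 * n_res, 2.8, 3.8), 3),
    lj_epsilon = round(runif(2 * n_res, 0.05, 0.3), 3),
    stringsAsFactors = FALSE)
  sm <- structure_model(atoms)
  nf <- 4
  coords <- array(rnorm(nf * 2 * n_res * 3, sd = 4), c(nf, 2 * n_res, 3))
  coords[, , 1] <- coords[, , 1] +
    rep(ifelse(atoms$chain_id == "A", 0, 9), each = nf)
  traj <- trajectory(sm, coords)
  enz <- which(atoms$chain_id == "A")
  sub <- which(atoms$chain_id == "B")
  params <- nonbonded_params(dielectric = 4)
  dec <- interface_decomposition(traj, enz, sub, params = params)

  # oracle: plain loops over frames and atom pairs
  vdw_res <- numeric(n_res); cou_res <- numeric(n_res)
  tot_vdw <- 0; tot_cou <- 0
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (i in enz) for (j in sub) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sij <- (atoms$lj_sigma[i] + atoms$lj_sigma[j]) / 2
      eij <- sqrt(atoms$lj_epsilon[i] * atoms$lj_epsilon[j])
      v <- 4 * eij * ((sij / r)^12 - (sij / r)^6)
      cq <- 332.0636 * atoms$charge[i] * atoms$charge[j] / (4 * r)
      ri <- atoms$residue_number[i]
      vdw_res[ri] <- vdw_res[ri] + v / nf
      cou_res[ri] <- cou_res[ri] + cq / nf
      tot_vdw <- tot_vdw + v / nf
      tot_cou <- tot_cou + cq / nf
    }
  }
  enz_rows <- dec[dec$side == "enzyme", ]
  m <- match(enz_rows$residue_number, seq_len(n_res))
  expect_equal(enz_rows$vdw, vdw_res[m], tolerance = 1e-9)
  expect_equal(enz_rows$coulomb, cou_res[m], tolerance = 1e-9)
  expect_true(all(abs(enz_rows$total - enz_rows$vdw - enz_rows$coulomb)
                  < 1e-9))
  expect_false(is.unsorted(dec$total))

  tot <- interface_totals(dec)
  expect_equal(tot$vdw, rep(tot_vdw, 2), tolerance = 1e-9)
  expect_equal(tot$coulomb, rep(tot_cou, 2), tolerance = 1e-9)
  expect_equal(sum(enz_rows$total), tot$total[1], tolerance = 1e-9)
})

test_that("zero parameters give zero energy and windows subset frames", {
  pk <- pocket_spec(3)
  sm <- pk$structure
  sm$atoms$charge <- 0
  sm$atoms$lj_epsilon <- 0
  pk$structure <- sm
  sim <- simulate_rotamer_trajectory(kinetics_preset("me3"), pk,
                                     n_frames = 10, seed = 28)
  enz <- which(sm$atoms$chain_id == "A")
  sub <- which(sm$atoms$chain_id == "B")
  dec0 <- interface_decomposition(sim$trajectory, enz, sub)
  expect_equal(max(abs(dec0$total)), 0)

  sim2 <- simulate_preset("me3", n_frames = 10, seed = 28)
  dec_w <- interface_decomposition(sim2$trajectory, enz, sub,
                                   window = c(3, 5))
  sub_traj <- trajectory(sim2$trajectory$structure,
                         sim2$trajectory$coords[3:5, , , drop = FALSE])
  dec_s <- interface_decomposition(sub_traj, enz, sub)
  expect_equal(dec_w$total, dec_s$total, tolerance = 1e-12)
  expect_equal(dec_w$frames_averaged, rep(3, nrow(dec_w)))
})
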
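test_that("candidate enumeration pairs hydrogens with their donors by name", {
  atoms <- data.frame(
    serial = 1:6,
    name = c("N", "H", "CA", "C", "O", "OG"),
    element = c("N", "H", "C", "C", "O", "O"),
    residue_name = c(rep("SER", 6)),
    residue_number = 1L, chain_id = "A", stringsAsFactors = FALSE)
  atoms$residue_number[5:6] <- 2L  # acceptors in the next residue
  sm <- structure_model(atoms)
  tr <- enumerate_dha_triples(sm, mode = "strict")
  expect_equal(nrow(tr), 2)  # N-H to O and to OG
  expect_true(all(tr$donor == 1))
  expect_setequal(tr$acceptor, c(5, 6))

  wat <- structure_model(data.frame(
    serial = 1:4,
    name = c("O", "H1", "H2", "O"),
    element = c("O", "H", "H", "O"),
    residue_name = c("HOH", "HOH", "HOH", "ALA"),
    residue_number = c(1L, 1L, 1L, 2L), chain_id = "W",
    stringsAsFactors = FALSE))
  trw <- enumerate_dha_triples(wat, mode = "strict")
  # two O-H donor pairs, each can reach the foreign acceptor only
  expect_equal(sum(trw$donor == 1 & trw$acceptor == 4), 2)

  m3 <- structure_model(data.frame(
    serial = 1:5,
    name = c("CZ1", "HZ11", "HZ12", "HZ13", "O"),
    element = c("C", "H", "H", "H", "O"),
    residue_name = c(rep("M3L", 4), "GLY"),
    residue_number = c(rep(9L, 4), 170L), chain_id = c(rep("B", 4), "A"),
    stringsAsFactors = FALSE))
  expect_equal(nrow(enumerate_dha_triples(m3, mode = "strict")), 0)
  cho <- enumerate_dha_triples(m3, mode = "cho")
  expect_equal(nrow(cho), 3)  # three C-H...O candidates
  expect_true(all(cho$donor == 1 & cho$acceptor == 5))

  noh <- structure_model(atoms[-2, ])
  expect_error(enumerate_dha_triples(noh), "no hydrogens")
})

test_that("frame detection applies the strict criteria exactly", {
  tri <- data.frame(donor = 1, hydrogen = 2, acceptor = 3)
  crit <- hbond_criteria()
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  expect_true(detect_frame(co, tri, crit))
  co[3, ] <- c(3.1, 0, 0)
  expect_false(detect_frame(co, tri, crit))
  # geometry engineered to theta = 110 with R < 3: rejected on angle alone
  u <- c(-cos(110 * pi / 180), sin(110 * pi / 180), 0)
  co3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0) + 1.8 * u)
  expect_lt(sqrt(sum((co3[3, ] - co3[1, ])^2)), 3)
  expect_false(detect_frame(co3, tri, crit))
})

test_that("occupancy census equals the exhaustive triple-loop oracle", {
  traj <- make_census_fixture(n_frames = 200, seed = 5)
  crit <- hbond_criteria(mode = "cho")
  triples <- enumerate_dha_triples(traj$structure, mode = "cho")
  expect_gt(nrow(triples), 20)
  rec <- hbond_occupancy(traj, triples, crit)
  sat <- oracle_hbond_census(traj, triples, crit$r_max, crit$theta_min)
  occ_oracle <- colMeans(sat)
  hit <- which(occ_oracle > 0)
  expect_equal(nrow(rec), length(hit))
  key <- paste(triples$donor, triples$hydrogen, triples$acceptor)
  expect_setequal(paste(rec$donor_idx, rec$hydrogen_idx, rec$acceptor_idx),
                  key[hit])
  m <- match(paste(rec$donor_idx, rec$hydrogen_idx, rec$acceptor_idx),
             key)
  expect_equal(rec$occupancy, occ_oracle[m], tolerance = 1e-12)
})

test_that("constructed fixture reports exactly its target occupancy", {
  tr <- make_hbond_fixture(0.6, 500, seed = 22)
  rec <- hbond_occupancy(tr)
  main <- rec[rec$donor == "B/ARG8/NH1" & rec$acceptor == "B/LYS9/O", ]
  expect_equal(main$occupancy, 0.600, tolerance = 1e-12)
  expect_equal(main$mean_distance, 2.8, tolerance = 1e-9)
  expect_equal(main$mean_linearity_deviation, 0, tolerance = 1e-9)
})

test_that("criteria tightening is monotone and strict is a subset of cho", {
  traj <- make_census_fixture(n_frames = 120, seed = 23)
  loose <- hbond_occupancy(traj, criteria = hbond_criteria(
    r_max = 3.4, mode = "cho"))
  tight <- hbond_occupancy(traj, criteria = hbond_criteria(
    r_max = 3.0, theta_min = 140, mode = "cho"))
  key <- function(r) paste(r$donor_idx, r$hydrogen_idx, r$acceptor_idx)
  expect_true(all(key(tight) %in% key(loose)))
  m <- match(key(tight), key(loose))
  expect_true(all(tight$occupancy <= loose$occupancy[m] + 1e-12))

  strict <- hbond_occupancy(traj, criteria = hbond_criteria(
    r_max = 3.4, mode = "strict"))
  expect_true(all(key(strict) %in% key(loose)))
  m2 <- match(key(strict), key(loose))
  expect_equal(strict$occupancy, loose$occupancy[m2])
})

test_that("detection is invariant under rigid motion of each frame", {
  traj <- make_census_fixture(n_frames = 40, seed = 24)
  moved <- traj$coords
  for (f in 1:40)
    moved[f, , ] <- sweep(rotate_about_axis(traj$coords[f, , ],
                                            c(0, 0, 0), c(1, 2, 3), 81),
                          2, c(10, -4, 2), "+")
  tr2 <- trajectory(traj$structure, moved)
  crit <- hbond_criteria(mode = "cho")
  r1 <- hbond_occupancy(traj, criteria = crit)
  r2 <- hbond_occupancy(tr2, criteria = crit)
  expect_equal(r1$occupancy, r2$occupancy, tolerance = 1e-9)
  expect_equal(r1$mean_distance, r2$mean_distance, tolerance = 1e-9)
})

test_that("bond classification follows chains, backbone flags and waters", {
  traj <- make_census_fixture(n_frames = 60, seed = 25)
  rec <- hbond_occupancy(traj, criteria = hbond_criteria(mode = "cho"))
  rec <- classify_bond(rec, traj$structure, substrate_chain = "B",
                       enzyme_chain = "A")
  expect_true(all(rec$span_class %in%
    c("interface", "intra-substrate", "intra-enzyme", "water-mediated",
      "water-substrate", "water-enzyme")))
  # backbone N donors are main chain, methyl C donors side chain
  expect_true(all(rec$donor_class[grepl("/N$", rec$donor)] == "main chain"))
  expect_true(all(rec$donor_class[grepl("CZ1$", rec$donor)] ==
                  "side chain"))

  # the motivating intra-substrate case: Arg8 side chain to Lys9 main chain
  fx <- make_hbond_fixture(1, 10, seed = 26)
  r <- classify_bond(hbond_occupancy(fx), fx$structure, "B", "A")
  main <- r[r$donor == "B/ARG8/NH1" & r$acceptor == "B/LYS9/O", ]
  expect_equal(main$donor_class, "side chain")
  expect_equal(main$acceptor_class, "main chain")
  expect_equal(main$span_class, "intra-substrate")

  expect_error(classify_bond(r, fx$structure, substrate_chain = "Q",
                             enzyme_chain = "A"), "neither declared chain")
})
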
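test_that("PDB parsing keeps file order, fields and altLoc A only", {
  sm <- read_structure(write_mini_pdb())
  expect_equal(nrow(sm$atoms), 3)
  expect_equal(sm$atoms$name, c("N", "CA", "C"))
  expect_equal(sm$atoms$residue_number, rep(7L, 3))
  expect_equal(sm$atoms$chain_id, rep("B", 3))
  expect_equal(attr(sm, "coords")[1, ], c(1, 2, 3))
  expect_true(all(sm$atoms$backbone))

  lines <- c(pdb_line(1, "CA", "ALA", "B", 7, 0, 0, 0, alt = "A",
                      element = "C"),
             pdb_line(2, "CA", "ALA", "B", 7, 9, 9, 9, alt = "B",
                      element = "C"),
             pdb_line(3, "O", "ALA", "B", 7, 1, 1, 1, element = "O"),
             "END")
  sm2 <- read_structure(write_mini_pdb(lines))
  expect_equal(nrow(sm2$atoms), 2)
  expect_equal(attr(sm2, "coords")[1, ], c(0, 0, 0))
})

test_that("HETATM Fe resolves element and is not backbone", {
  lines <- c(mini_pdb_text()[1:3],
             pdb_line(9, "FE", "FE2", "A", 400, 5, 5, 5, record = "HETATM",
                      element = "FE"),
             "END")
  sm <- read_structure(write_mini_pdb(lines))
  fe <- sm$atoms[sm$atoms$name == "FE", ]
  expect_equal(toupper(fe$element), "FE")
  expect_false(fe$backbone)
})

test_that("malformed and duplicate-serial PDB input fail loudly", {
  bad <- c(mini_pdb_text()[1], "ATOM      2  CA ALA B   7  garbage", "END")
  expect_error(read_structure(write_mini_pdb(bad)), "line 2")
  dup <- c(pdb_line(1, "N", "ALA", "B", 7, 0, 0, 0, element = "N"),
           pdb_line(1, "CA", "ALA", "B", 7, 1, 0, 0, element = "C"),
           pdb_line(3, "C", "ALA", "B", 7, 2, 0, 0, element = "C"),
           "END")
  expect_error(read_structure(write_mini_pdb(dup)), "duplicate")
})

test_that("trajectory readers honour frame order, dt and count contracts", {
  sm <- read_structure(write_mini_pdb())

  mm <- c("MODEL        1", mini_pdb_text()[1:3], "ENDMDL", "END")
  tr <- read_trajectory(write_mini_pdb(mm), sm, dialect = "pdb", dt = 1)
  expect_equal(n_frames(tr), 1)
  expect_equal(frame_coords(tr, 1), attr(sm, "coords"), tolerance = 1e-9)

  xyz_path <- tempfile(fileext = ".xyz")
  con <- file(xyz_path, "w")
  for (f in 1:5)
    writeLines(c("3", paste("frame", f),
                 sprintf("%s %f %f %f", c("N", "C", "C"), f + 0:2, 0, 0)),
               con)
  close(con)
  tr5 <- read_trajectory(xyz_path, sm, dialect = "xyz", dt = 2)
  expect_equal(tr5$times, c(0, 2, 4, 6, 8))
  expect_equal(tr5$coords[3, 1, 1], 3)

  short <- c("MODEL 1", mini_pdb_text()[1:3], "ENDMDL",
             "MODEL 2", mini_pdb_text()[1:3], "ENDMDL",
             "MODEL 3", mini_pdb_text()[1:2], "ENDMDL", "END")
  expect_error(read_trajectory(write_mini_pdb(short), sm, dialect = "pdb"),
               "frame 3")
})

test_that("parameter sidecar joins by (residue, atom) and reports misses", {
  sm <- read_structure(write_mini_pdb())
  tab <- data.frame(residue_name = c("ALA", "M3L"), atom_name = c("N", "NZ"),
                    charge = c(-0.3, 1.0), lj_sigma = c(3.25, 3.25),
                    lj_epsilon = c(0.17, 0.17), vdw_radius = c(1.55, 1.55))
  p <- tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE)
  expect_warning(sm2 <- read_parameters(sm, p), "M3L NZ")
  expect_equal(sm2$atoms$charge[1], -0.3)
  expect_true(all(is.na(sm2$atoms$charge[2:3])))
  expect_equal(attr(sm2, "unmatched_atoms"), 2:3)

  write.csv(tab[0, ], p, row.names = FALSE)
  sm3 <- read_parameters(sm, p)
  expect_true(all(is.na(sm3$atoms$charge)))
  expect_equal(attr(sm3, "unmatched_atoms"), 1:3)

  write.csv(rbind(tab, tab[1, ]), p, row.names = FALSE)
  expect_error(read_parameters(sm, p), "duplicate")
})

test_that("the packaged parameter sidecar covers the trimethyl pocket", {
  path <- system.file("extdata", "pocket_params.csv", package = "pocketdyn")
  pk <- pocket_spec(3)
  sm <- pk$structure
  sm$atoms$charge <- NA_real_
  sm2 <- suppressWarnings(read_parameters(structure_model(sm$atoms[
    setdiff(names(sm$atoms), "backbone")], sm$title), path))
  expect_length(attr(sm2, "unmatched_atoms"), 0)
  # water rows are spare capacity for the me1/me2 pockets
  expect_true(all(grepl("^HOH", attr(sm2, "unmatched_keys"))))
  expect_equal(sm2$atoms$charge[sm2$atoms$name == "FE"], 2.0)
  expect_equal(sm2$atoms$vdw_radius[sm2$atoms$name == "NZ"], 1.55)
})

test_that("selections resolve deterministically and never return silent emptiness", {
  pk <- pocket_spec(3)
  sel <- resolve_selection(pk$structure, chain = "B", residues = 9,
                           names = c("CZ1", "CZ2", "CZ3"))
  expect_length(sel, 3)
  expect_false(is.unsorted(sel))
  # clause order / duplication never changes the result
  sel2 <- resolve_selection(pk$structure, names = c("CZ3", "CZ2", "CZ1"),
                            residues = c(9, 9), chain = "B")
  expect_equal(as.integer(sel), as.integer(sel2))
  expect_error(resolve_selection(pk$structure, names = "CZ9"),
               "empty selection")

  pep <- make_peptide_fixture(5)
  bb <- resolve_selection(pep, chain = "B", backbone = TRUE)
  expect_true(all(pep$atoms$backbone[bb]))
  expect_length(bb, 20)
})

test_that("PDB and XYZ round trips preserve coordinates at format precision", {
  sim <- simulate_preset("me3", n_frames = 3, seed = 11)
  traj <- sim$trajectory

  pdb_path <- tempfile(fileext = ".pdb")
  write_pdb(traj, pdb_path)
  sm2 <- read_structure(pdb_path)
  tr2 <- read_trajectory(pdb_path, sm2, dialect = "pdb", dt = traj$dt)
  expect_equal(n_frames(tr2), 3)
  expect_equal(tr2$coords, traj$coords, tolerance = 1e-3)
  expect_true(max(abs(tr2$coords - traj$coords)) <= 5e-4 + 1e-12)

  xyz_path <- tempfile(fileext = ".xyz")
  write_xyz(traj, xyz_path)
  tr3 <- read_trajectory(xyz_path, traj$structure, dialect = "xyz",
                         dt = traj$dt)
  expect_equal(tr3$coords, traj$coords, tolerance = 1e-6)
})
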
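test_that("occupancy counts strict inclusion and matches brute force", {
  pep <- make_peptide_fixture(4)
  ref <- attr(pep, "coords")
  nf <- 30
  coords <- array(rep(as.numeric(ref), each = nf), c(nf, nrow(ref), 3))
  # put atom 2 at a fixed distance from atom 1
  place_at <- function(coords, d) {
    coords[, 2, ] <- 0
    coords[, 1, ] <- 0
    coords[, 2, 1] <- d
    coords
  }
  tr <- trajectory(pep, place_at(coords, 4.0))
  r <- occupancy_frequency(tr, 1, 2, radius = 4.7)
  expect_equal(unname(r$per_atom_fraction), 1)
  expect_equal(r$union_fraction, 1)
  tr2 <- trajectory(pep, place_at(coords, 5.0))
  r2 <- occupancy_frequency(tr2, 1, 2, radius = 4.7)
  expect_equal(r2$sum_fraction, 0)
  # boundary: strict inequality
  tr3 <- trajectory(pep, place_at(coords, 4.7))
  expect_equal(occupancy_frequency(tr3, 1, 2, 4.7)$union_fraction, 0)

  sim <- simulate_preset("me3", n_frames = 400, seed = 17)
  pk <- sim$pocket
  occ <- occupancy_frequency(sim$trajectory, pk$fe_atom, pk$head_atoms$CZ,
                             4.7)
  # frame/atom brute force
  counts <- rep(0, 3)
  union <- 0
  for (f in seq_len(400)) {
    xyz <- frame_coords(sim$trajectory, f)
    inside <- vapply(pk$head_atoms$CZ, function(i)
      sqrt(sum((xyz[i, ] - xyz[pk$fe_atom, ])^2)) < 4.7, logical(1))
    counts <- counts + inside
    union <- union + any(inside)
  }
  expect_equal(unname(occ$per_atom_fraction), counts / 400)
  expect_equal(occ$union_fraction, union / 400)
  expect_equal(occ$sum_fraction, sum(counts) / 400)
  expect_error(occupancy_frequency(sim$trajectory, pk$fe_atom, integer(0)),
               "empty target")
})

test_that("radius sweeps are monotone and reduce to single calls", {
  sim <- simulate_preset("me2", n_frames = 300, seed = 18)
  pk <- sim$pocket
  sw <- radius_sweep(sim$trajectory, pk$fe_atom, pk$head_atoms$CZ)
  u <- vapply(sw, function(r) r$union_fraction, numeric(1))
  expect_true(all(diff(u) >= 0))
  one <- radius_sweep(sim$trajectory, pk$fe_atom, pk$head_atoms$CZ,
                      radii = 4.7)
  expect_equal(one[[1]]$per_atom_fraction,
               occupancy_frequency(sim$trajectory, pk$fe_atom,
                                   pk$head_atoms$CZ, 4.7)$per_atom_fraction)

  # a target walking across the 4.7 A shell: strictly increasing fractions
  pep <- make_peptide_fixture(4)
  nf <- 200
  coords <- array(0, c(nf, nrow(attr(pep, "coords")), 3))
  coords[, 2, 1] <- seq(4.55, 4.85, length.out = nf)
  trw <- trajectory(pep, coords)
  sww <- radius_sweep(trw, 1, 2)
  uw <- vapply(sww, function(r) r$union_fraction, numeric(1))
  expect_true(all(diff(uw) > 0))
  expect_error(radius_sweep(trw, 1, 2, radii = c(4.8, 4.6)), "sorted")
})

test_that("union <= min(1, sum) on random fixtures and under rigid motion", {
  pep <- make_peptide_fixture(5)
  n <- nrow(attr(pep, "coords"))
  set.seed(19)
  for (k in 1:5) {
    coords <- array(rnorm(60 * n * 3, sd = 3), c(60, n, 3))
    tr <- trajectory(pep, coords)
    occ <- occupancy_frequency(tr, 1, 2:8, radius = 3.5)
    expect_lte(occ$union_fraction, min(1, occ$sum_fraction) + 1e-12)
    expect_true(all(occ$per_atom_fraction >= 0 & occ$per_atom_fraction <= 1))

    moved <- coords
    for (f in 1:60)
      moved[f, , ] <- sweep(rotate_about_axis(coords[f, , ], c(1, 1, 1),
                                              c(0, 0, 1), 123), 2,
                            c(8, -2, 5), "+")
    occ2 <- occupancy_frequency(trajectory(pep, moved), 1, 2:8,
                                radius = 3.5)
    expect_equal(occ2$per_atom_fraction, occ$per_atom_fraction)
  }
})

test_that("distance statistics match closed forms and the direct oracle", {
  pep <- make_peptide_fixture(4)
  n <- nrow(attr(pep, "coords"))
  nf <- 50
  coords <- array(0, c(nf, n, 3))
  coords[, 2, 1] <- 3.08
  ds <- distance_stats(trajectory(pep, coords), 1, 2)
  expect_equal(ds$mean, 3.08)
  expect_equal(ds$std, 0)

  coords[, 2, 1] <- rep(c(2, 4), nf / 2)
  ds2 <- distance_stats(trajectory(pep, coords), 1, 2)
  expect_equal(ds2$mean, 3)
  expect_equal(ds2$std, 1)

  set.seed(20)
  coords[, 1, ] <- rnorm(nf * 3, 0, 0.2)
  coords[, 2, ] <- coords[, 2, ] + rnorm(nf * 3, 0, 0.2)
  tr <- trajectory(pep, coords)
  ds3 <- distance_stats(tr, 1, 2)
  direct <- vapply(seq_len(nf), function(f)
    sqrt(sum((frame_coords(tr, f)[1, ] - frame_coords(tr, f)[2, ])^2)),
    numeric(1))
  expect_equal(ds3$series, direct, tolerance = 1e-12)
  expect_equal(ds3$mean, mean(direct), tolerance = 1e-12)
  expect_equal(ds3$std, sqrt(mean((direct - mean(direct))^2)),
               tolerance = 1e-12)
  expect_error(distance_stats(tr, 2, 2), "distinct")
})

test_that("preset pockets reproduce the expected distance regimes", {
  # symmetric cage: all NZ-O distances 4.2; asymmetric pulls two to 3.1
  pk3 <- pocket_spec(3)
  co <- pk3$base_coords
  nz <- pk3$head_atoms$NZ
  ox <- which(pk3$structure$atoms$element == "O" &
              pk3$structure$atoms$chain_id == "A")
  d3 <- sqrt(rowSums(sweep(co[ox, ], 2, co[nz, ])^2))
  expect_equal(d3, rep(4.2, length(ox)), tolerance = 1e-9)

  pk2 <- pocket_spec(2)
  a2 <- pk2$structure$atoms
  co2 <- pk2$base_coords
  pulled <- which(a2$name %in% c("OD1", "O") & a2$chain_id == "A")
  d2 <- sqrt(rowSums(sweep(co2[pulled, ], 2,
                           co2[pk2$head_atoms$NZ, ])^2))
  expect_equal(d2, rep(3.1, 2), tolerance = 1e-9)

  # waters coordinate Fe at 2.15 A in the lower methylation states
  sim <- simulate_preset("me1", n_frames = 500, seed = 21)
  pk <- sim$pocket
  for (w in pk$water_atoms) {
    dw <- distance_stats(sim$trajectory, pk$fe_atom, w)
    expect_equal(dw$mean, 2.15, tolerance = 0.05)
    expect_lt(dw$std, 0.15)
  }
  expect_lt(mean_fluctuation(sim$trajectory, pk$fe_atom), 1)
})
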
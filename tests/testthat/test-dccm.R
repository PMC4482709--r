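test_that("dccm definition cases: self-correlation 1, mirrored motion -1", {
  topo <- mol_structure(data.frame(name = "CA", resname = "GLY", chain = "A",
                                   resseq = 1:3, x = c(0, 10, 20), y = 0, z = 0))
  set.seed(3)
  base <- coords(topo)
  frames <- lapply(1:40, function(f) {
    d <- rnorm(3)
    fr <- base
    fr[1, ] <- fr[1, ] + d
    fr[2, ] <- fr[2, ] - d          # exactly anti-correlated with atom 1
    fr[3, ] <- fr[3, ] + rnorm(3)
    fr
  })
  cm <- dccm(mol_trajectory(topo, frames))
  expect_equal(diag(unclass(cm)), setNames(rep(1, 3), rownames(cm)))
  expect_equal(unclass(cm)[1, 2], -1, tolerance = 1e-12)
  expect_lt(max(abs(cm - t(unclass(cm)))), 1e-12)
  expect_true(all(cm >= -1 & cm <= 1))
})

test_that("dccm matches an independently coded covariance loop", {
  b <- make_helical_bundle(3, 4)
  sim <- simulate_correlated_trajectory(
    b, n_frames = 25, blocks = data.frame(helix_a = 1, helix_b = 3, rho = 0.6),
    seed = 10)
  cm <- dccm(sim$trajectory)
  want <- oracle_dccm(sim$trajectory$frames, seq_len(12))
  expect_lt(max(abs(unclass(cm) - want)), 1e-10)
})

test_that("dccm agrees with bio3d's implementation on a small trajectory", {
  b <- make_helical_bundle(3, 5)
  sim <- simulate_correlated_trajectory(
    b, n_frames = 30, blocks = data.frame(helix_a = 1, helix_b = 2, rho = -0.4),
    seed = 22)
  cm <- dccm(sim$trajectory)
  F <- n_frames(sim$trajectory)
  xyz <- t(vapply(seq_len(F), function(f) {
    as.numeric(t(frame_coords(sim$trajectory, f)))
  }, numeric(3 * n_atoms(b))))
  ref <- bio3d::dccm.xyz(xyz)
  expect_lt(max(abs(unclass(cm) - unclass(ref))), 1e-6)
})

test_that("planted block correlations are recovered within sampling error", {
  b <- make_helical_bundle(7, 20)
  blocks <- data.frame(helix_a = c(6, 2), helix_b = c(7, 7), rho = c(0.8, -0.5))
  sim <- simulate_correlated_trajectory(b, n_frames = 4000, blocks = blocks,
                                        seed = 123)
  cm <- dccm(sim$trajectory)
  hr <- sim$helix_ranges
  blk <- function(a, b2) {
    mean(unclass(cm)[seq(hr[[a]][1], hr[[a]][2]), seq(hr[[b2]][1], hr[[b2]][2])])
  }
  expect_lt(abs(blk(6, 7) - 0.8), 0.05)
  expect_lt(abs(blk(2, 7) + 0.5), 0.05)
  expect_lt(abs(blk(1, 4)), 0.05)
})

test_that("dccm is invariant to one global rigid transform", {
  b <- make_helical_bundle(4, 6)
  sim <- simulate_correlated_trajectory(b, n_frames = 60, seed = 5)
  cm <- dccm(sim$trajectory)
  tf <- structure(list(rotation = rotation_axis_angle(c(1, -2, 4), 35),
                       translation = c(3, 3, -9), rmsd = 0),
                  class = "rigid_transform")
  cm2 <- dccm(apply_transform(tf, sim$trajectory))
  expect_lt(max(abs(unclass(cm) - unclass(cm2))), 1e-10)
})

test_that("zero-variance atoms yield NA rows with a warning, diagonal kept", {
  topo <- mol_structure(data.frame(name = "CA", resname = "GLY", chain = "A",
                                   resseq = 1:3, x = c(0, 5, 10), y = 0, z = 0))
  base <- coords(topo)
  set.seed(2)
  frames <- lapply(1:10, function(f) {
    fr <- base
    fr[2:3, ] <- fr[2:3, ] + matrix(rnorm(6), 2, 3)
    fr  # atom 1 never moves
  })
  expect_warning(cm <- dccm(mol_trajectory(topo, frames)), "zero displacement")
  expect_true(all(is.na(unclass(cm)[1, -1])))
  expect_equal(unclass(cm)[1, 1], 1)
})

test_that("region reports separate planted, null, and anticorrelated blocks", {
  b <- make_helical_bundle(7, 10)
  blocks <- data.frame(helix_a = c(6, 2), helix_b = c(7, 7), rho = c(0.8, -0.5))
  sim <- simulate_correlated_trajectory(b, n_frames = 3000, blocks = blocks,
                                        seed = 17)
  cm <- dccm(sim$trajectory)
  hr <- sim$helix_ranges
  rng <- function(h) seq(hr[[h]][1], hr[[h]][2])

  high <- region_pair_report(cm, rng(6), rng(7))
  expect_equal(nrow(high$high_pairs), 100L)  # every cross pair planted
  expect_equal(nrow(high$low_pairs), 0L)

  null <- region_pair_report(cm, rng(1), rng(4))
  expect_equal(nrow(null$high_pairs), 0L)

  neg <- region_pair_report(cm, rng(2), rng(7))
  expect_equal(nrow(neg$low_pairs), 100L)
  expect_equal(nrow(neg$high_pairs), 0L)

  expect_error(region_pair_report(cm, 999, rng(7)), "empty region")
})

test_that("identity-like matrices produce empty region reports", {
  b <- make_helical_bundle(4, 8)
  sim <- simulate_correlated_trajectory(b, n_frames = 2000, seed = 44)
  cm <- dccm(sim$trajectory)
  hr <- sim$helix_ranges
  rp <- region_pair_report(cm, seq(hr[[1]][1], hr[[1]][2]),
                           seq(hr[[3]][1], hr[[3]][2]))
  expect_equal(nrow(rp$high_pairs), 0L)
})

test_that("correlation painting writes the anchor row into B-factors", {
  b <- make_helical_bundle(3, 6)
  sim <- simulate_correlated_trajectory(
    b, n_frames = 50, blocks = data.frame(helix_a = 1, helix_b = 2, rho = 0.9),
    seed = 3)
  cm <- dccm(sim$trajectory)
  painted <- correlation_to_structure(cm, b, anchor_resseq = 1)
  expect_equal(painted$atoms$bfactor[1], 1)
  expect_equal(painted$atoms$bfactor[-1], unclass(cm)[1, -1],
               ignore_attr = TRUE)
  # round trip through PDB keeps the values to the format's 2 decimals
  back <- read_pdb(write_pdb(painted))
  expect_lt(max(abs(back$atoms$bfactor - painted$atoms$bfactor)), 0.005 + 1e-9)

  missing <- mol_structure(data.frame(name = "CA", resname = "GLY",
                                      chain = "A", resseq = 999L,
                                      x = 0, y = 0, z = 0))
  expect_message(p2 <- correlation_to_structure(cm, missing, 1),
                 "absent")
  expect_equal(p2$atoms$bfactor, 0)
})
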
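test_that("helical bundle has the stated geometry", {
  b <- make_helical_bundle(7, 20)
  expect_equal(n_atoms(b), 140L)
  hr <- attr(b, "helix_ranges")
  expect_length(hr, 7L)
  all_res <- unname(unlist(lapply(hr, function(r) seq(r[1], r[2]))))
  expect_identical(sort(all_res), 1:140)

  # consecutive CA-CA distance from ideal helix geometry: 3.8 +/- 0.3
  for (h in c(1, 4, 7)) {
    idx <- resolve_selection(b, atom_selection(resseq = seq(hr[[h]][1], hr[[h]][2])))
    xyz <- coords(b)[idx, ]
    d <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_true(all(abs(d - 3.8) <= 0.3))
  }

  # two helices at radius 10: axis separation 20
  b2 <- make_helical_bundle(2, 36, bundle_radius = 10)
  hr2 <- attr(b2, "helix_ranges")
  ax <- function(r) colMeans(coords(b2)[resolve_selection(
    b2, atom_selection(resseq = seq(r[1], r[2]))), 1:2])
  expect_equal(sqrt(sum((ax(hr2[[1]]) - ax(hr2[[2]]))^2)), 20, tolerance = 0.1 / 20)
})

test_that("correlated-trajectory generator is deterministic and honours rho = 1", {
  b <- make_helical_bundle(7, 5)
  blocks <- data.frame(helix_a = 6, helix_b = 7, rho = 1)
  s1 <- simulate_correlated_trajectory(b, n_frames = 50, blocks = blocks, seed = 9)
  s2 <- simulate_correlated_trajectory(b, n_frames = 50, blocks = blocks, seed = 9)
  expect_identical(s1$trajectory$frames, s2$trajectory$frames)

  # rho = 1, no rigid noise: paired helices' displacement vectors identical
  # (to the numerical precision of the covariance square root)
  hr <- s1$helix_ranges
  base <- coords(b)
  i6 <- resolve_selection(b, atom_selection(resseq = seq(hr[[6]][1], hr[[6]][2])))
  i7 <- resolve_selection(b, atom_selection(resseq = seq(hr[[7]][1], hr[[7]][2])))
  for (f in c(1, 25, 50)) {
    d <- frame_coords(s1$trajectory, f) - base
    expect_lt(max(abs(d[i6, ] - d[i7, ])), 1e-6)
  }
})

test_that("non-PSD correlation specs are rejected", {
  b <- make_helical_bundle(3, 4)
  bad <- data.frame(helix_a = c(1, 1, 2), helix_b = c(2, 3, 3),
                    rho = c(0.9, 0.9, -0.9))
  expect_error(simulate_correlated_trajectory(b, n_frames = 5, blocks = bad),
               "positive semi-definite")
  expect_error(simulate_correlated_trajectory(
    b, n_frames = 5, blocks = data.frame(helix_a = 1, helix_b = 2, rho = 1.2)),
    "rho")
})

test_that("water scene plants densities, labels, and parks unused slots away", {
  wire <- straight_wire(20, 20, z_from = 2, z_to = 38, spacing = 2.8)
  sc <- make_water_scene(c(0, 0, 0), c(40, 40, 40), 0.001, n_frames = 60,
                         wire = wire, wire_frames = 1:10,
                         slab_low = c(0, 5), slab_high = c(35, 40), seed = 4)
  # Poisson mean 0.001 * 64000 = 64; 5 sigma over 60 frames
  expect_lt(abs(mean(sc$n_background) - 64), 5 * sqrt(64 / 60))
  expect_identical(sc$spanning, seq_len(60) %in% 1:10)

  # empty scene has no waters in the box in any frame
  empty <- make_water_scene(c(0, 0, 0), c(20, 20, 20), 0, n_frames = 3, seed = 1)
  for (f in 1:3) {
    xyz <- frame_coords(empty$trajectory, f)
    inside <- xyz[, 1] >= 0 & xyz[, 1] <= 20 & xyz[, 3] >= 0 & xyz[, 3] <= 20
    expect_equal(sum(inside), 0L)
  }

  expect_error(make_water_scene(c(0, 0, 0), c(10, 10, 10), 0.001, n_frames = 2,
                                wire = rbind(c(5, 5, 5), c(5, 5, 15)),
                                wire_frames = 1),
               "outside the box")
  expect_error(make_water_scene(c(0, 0, 0), c(10, 10, 10), 0.001, n_frames = 2,
                                wire = rbind(c(5, 5, 1), c(5, 5, 9)),
                                wire_frames = 1),
               "spacing bound")
})

test_that("two-state generator: absorbing case, determinism, noise model", {
  abs1 <- simulate_two_state_distance(n_frames = 200, p_stay = 1, seed = 2)
  expect_true(all(abs1$states))
  expect_equal(abs1$occupancy, 1.0)
  expect_lt(max(abs(abs1$series$distance - 2.8)), 5 * 0.2)

  a <- simulate_two_state_distance(n_frames = 500, p_stay = 0.95, seed = 3)
  b <- simulate_two_state_distance(n_frames = 500, p_stay = 0.95, seed = 3)
  expect_identical(a$series$distance, b$series$distance)
  expect_identical(a$states, b$states)
  expect_equal(a$occupancy, mean(a$states))
  expect_error(simulate_two_state_distance(d_formed = 9, d_broken = 8),
               "d_formed")
})

test_that("toy retinal: planted dihedrals, bond lengths, shared anchors", {
  for (conf in c("trans", "cis")) {
    s <- make_toy_retinal(conf)
    a <- s$atoms
    g <- function(n) as.numeric(a[a$name == n, c("x", "y", "z")])
    dih <- oracle_dihedral(g("C12"), g("C13"), g("C14"), g("C15"))
    want <- if (conf == "trans") 180 else 0
    expect_lt(min(abs(dih - want), abs(dih + want)), 1e-6)

    bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"),
                  c("CE", "NZ"), c("NZ", "C15"), c("C13", "C14"),
                  c("C7", "C1"), c("C1", "C2"), c("C6", "C1"))
    for (bd in bonds) {
      len <- sqrt(sum((g(bd[1]) - g(bd[2]))^2))
      expect_true(len >= 1.4 - 1e-9 && len <= 1.6 + 1e-9,
                  label = paste(conf, bd[1], bd[2], "=", round(len, 3)))
    }
  }
  expect_identical(attr(make_toy_retinal("trans"), "anchors"),
                   attr(make_toy_retinal("cis"), "anchors"))
  expect_error(make_toy_retinal("twisted"))
})
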
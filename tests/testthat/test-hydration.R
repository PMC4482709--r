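single_water_trajectory <- function(positions, dt = 0.1) {
  topo <- mol_structure(data.frame(name = "O", resname = "HOH", chain = "W",
                                   resseq = 1L, x = 0, y = 0, z = 0,
                                   hetatm = TRUE))
  mol_trajectory(topo, lapply(positions, function(p) matrix(p, 1, 3)), dt)
}

test_that("density normalisation follows the declared closed form", {
  # one stationary water, 100 frames of 0.1 ns, 1 A^3 voxels:
  # value = 100 / (1 * 100 * 0.1) = 10 molecules A^-3 ns^-1 in its voxel
  traj <- single_water_trajectory(rep(list(c(2.5, 2.5, 2.5)), 100))
  dg <- water_density(traj, grid_spec(c(0, 0, 0), 1, c(5, 5, 5)))
  expect_equal(dg$values[3, 3, 3], 10)
  expect_equal(sum(dg$values > 0), 1L)
  # conservation: sum * voxel_vol * total_ns = total in-grid counts
  expect_equal(sum(dg$values) * 1 * (100 * 0.1), 100)

  # empty scene: all-zero grid
  empty <- make_water_scene(c(0, 0, 0), c(10, 10, 10), 0, n_frames = 4, seed = 2)
  dg0 <- water_density(empty$trajectory, grid_spec(c(0, 0, 0), 1, c(10, 10, 10)))
  expect_true(all(dg0$values == 0))
})

test_that("density conservation holds exactly on random scenes and recovers rho", {
  set.seed(40)
  for (rep in 1:6) {
    sc <- make_water_scene(c(0, 0, 0), c(20, 20, 20),
                           background_density = runif(1, 5e-4, 5e-3),
                           n_frames = sample(5:20, 1),
                           seed = sample.int(1e6, 1))
    gs <- grid_spec(c(0, 0, 0), 2, c(10, 10, 10))
    dg <- water_density(sc$trajectory, gs)
    total_ns <- dg$n_frames * dg$frame_interval_ns
    expect_equal(sum(dg$values) * 2^3 * total_ns, sum(dg$counts))
    expect_equal(sum(dg$counts), sum(sc$n_background))
  }

  # uniform scene: mean occupancy density recovers planted rho within 4 sigma
  rho <- 0.001
  sc <- make_water_scene(c(0, 0, 0), c(40, 40, 40), rho, n_frames = 50, seed = 99)
  dg <- water_density(sc$trajectory, grid_spec(c(0, 0, 0), 1, c(40, 40, 40)),
                      per_frame_average = TRUE)
  est <- mean(dg$values)
  n_tot <- rho * 40^3 * 50
  expect_lt(abs(est - rho), 4 * sqrt(n_tot) / (40^3 * 50))
})

test_that("iso-level masks equal a brute-force scan and shrink with level", {
  set.seed(41)
  vals <- array(rexp(27, 10), dim = c(3, 3, 3))
  g <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(3L, 3L, 3L),
                      values = vals), class = "density_grid")
  for (lev in c(0, 0.05, 0.2, max(vals) + 1)) {
    m <- iso_level_mask(g, lev)
    expect_equal(m$count, sum(vals >= lev))
    expect_identical(m$mask, vals >= lev)
  }
  counts <- vapply(c(0, 0.01, 0.1, 0.5), function(l) iso_level_mask(g, l)$count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("water wire finds planted chains and respects gaps", {
  wire <- straight_wire(5, 5, z_from = 1, z_to = 29, spacing = 2.8)
  res <- water_wire(wire, c(0, 2), c(28, 30), cutoff = 3.5)
  expect_true(res$spanning)
  expect_identical(res$path, seq_len(nrow(wire)))
  # consecutive path nodes within cutoff, endpoints in slabs
  pxyz <- wire[res$path, ]
  gaps <- sqrt(rowSums((pxyz[-1, ] - pxyz[-nrow(pxyz), ])^2))
  expect_true(all(gaps <= 3.5))
  expect_true(pxyz[1, 3] <= 2 && pxyz[nrow(pxyz), 3] >= 28)

  broken <- wire[-5, ]  # removes ~2.8+2.8 -> 5.6 A gap
  expect_false(water_wire(broken, c(0, 2), c(28, 30), cutoff = 3.5)$spanning)
  expect_true(water_wire(broken, c(0, 2), c(28, 30), cutoff = 6)$spanning)
  expect_false(water_wire(matrix(numeric(0), 0, 3), c(0, 2), c(28, 30))$spanning)
  expect_error(water_wire(wire, c(0, 10), c(5, 20)), "disjoint")
})

test_that("spanning decisions equal the union-find oracle on random scenes", {
  set.seed(42)
  agree <- 0L
  for (rep in 1:30) {
    n <- sample(10:40, 1)
    xyz <- cbind(runif(n, 0, 15), runif(n, 0, 15), runif(n, 0, 30))
    got <- water_wire(xyz, c(0, 4), c(26, 30), cutoff = 3.5)$spanning
    want <- oracle_spanning(xyz, c(0, 4), c(26, 30), 3.5)
    expect_identical(got, want)
    agree <- agree + 1L
  }
  expect_equal(agree, 30L)
})

test_that("spanning is monotone in cutoff and under adding waters", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(15:30, 1)
    xyz <- cbind(runif(n, 0, 12), runif(n, 0, 12), runif(n, 0, 25))
    sp <- vapply(c(2, 3, 4, 6, 9), function(co) {
      water_wire(xyz, c(0, 3), c(22, 25), cutoff = co)$spanning
    }, logical(1))
    expect_true(all(diff(sp) >= 0))
    # adding points never breaks spanning
    if (sp[3]) {
      more <- rbind(xyz, cbind(runif(5, 0, 12), runif(5, 0, 12), runif(5, 0, 25)))
      expect_true(water_wire(more, c(0, 3), c(22, 25), cutoff = 4)$spanning)
    }
  }
})

test_that("wire_fraction reports planted per-frame labels exactly", {
  wire <- straight_wire(20, 20, z_from = 2, z_to = 38, spacing = 2.8)
  sc <- make_water_scene(c(0, 0, 0), c(40, 40, 40), 0, n_frames = 20,
                         wire = wire, wire_frames = 1:10,
                         slab_low = c(0, 5), slab_high = c(35, 40), seed = 8)
  wr <- wire_fraction(sc$trajectory, c(0, 5), c(35, 40))
  expect_equal(wr$spanning_fraction, 0.5)
  expect_identical(wr$per_frame$spanning, sc$spanning)

  all_wire <- make_water_scene(c(0, 0, 0), c(40, 40, 40), 0, n_frames = 5,
                               wire = wire, wire_frames = 1:5,
                               slab_low = c(0, 5), slab_high = c(35, 40),
                               seed = 8)
  expect_equal(wire_fraction(all_wire$trajectory, c(0, 5),
                             c(35, 40))$spanning_fraction, 1.0)

  # low-density background with no wire: oracle-confirmed zero
  bg <- make_water_scene(c(0, 0, 0), c(40, 40, 40), 2e-4, n_frames = 10,
                         seed = 77)
  wr0 <- wire_fraction(bg$trajectory, c(0, 5), c(35, 40))
  oracle0 <- vapply(1:10, function(f) {
    xyz <- frame_coords(bg$trajectory, f)
    oracle_spanning(xyz[xyz[, 3] < 100, , drop = FALSE], c(0, 5), c(35, 40), 3.5)
  }, logical(1))
  expect_identical(wr0$per_frame$spanning, oracle0)
  expect_equal(wr0$spanning_fraction, mean(oracle0))
})

test_that("pore radii match the single-ring closed form and the dense scan", {
  # ring of N atoms at radius 8 in one slice; vdW O = 1.52
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- mol_structure(data.frame(
    name = "O", resname = "HOH", chain = "R", resseq = seq_along(th),
    x = 8 * cos(th), y = 8 * sin(th), z = 0, hetatm = TRUE))
  pp <- pore_radius_profile(ring, z_range = c(0, 0), slice_thickness = 1,
                            axis_xy = c(0, 0))
  expect_equal(pp$radius[1], 8 - 1.52, tolerance = 0.01 / (8 - 1.52))

  # empty structure: flagged at the search bound
  empty <- mol_structure(data.frame(name = character(0), resname = character(0),
                                    chain = character(0), resseq = integer(0),
                                    x = numeric(0), y = numeric(0),
                                    z = numeric(0)))
  pe <- pore_radius_profile(empty, z_range = c(0, 10), slice_thickness = 5,
                            axis_xy = c(0, 0), search_radius = 7)
  expect_true(all(pe$flagged))
  expect_true(all(pe$radius == 7))

  # random clouds vs dense radial scan
  set.seed(55)
  for (rep in 1:4) {
    n <- 25
    cl <- mol_structure(data.frame(
      name = sample(c("C", "N", "O"), n, replace = TRUE),
      resname = "UNK", chain = "X", resseq = seq_len(n),
      x = runif(n, -10, 10), y = runif(n, -10, 10), z = runif(n, -5, 5)))
    pp2 <- pore_radius_profile(cl, z_range = c(-4, 4), slice_thickness = 2,
                               axis_xy = c(0, 0), search_radius = 9)
    xyz <- coords(cl)
    rv <- vapply(cl$atoms$element,
                 function(e) c(C = 1.70, N = 1.55, O = 1.52)[[e]], numeric(1))
    for (i in seq_len(nrow(pp2))) {
      want <- oracle_pore_radius(c(0, 0, pp2$z[i]), xyz, rv, bound = 9)
      expect_lt(abs(pp2$radius[i] - want), 0.02)
    }
  }
})

test_that("pore radius shrinks when an atom moves toward the axis", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  mk <- function(r1) {
    mol_structure(data.frame(
      name = "C", resname = "UNK", chain = "X", resseq = seq_along(th),
      x = c(r1, rep(8, 7)) * cos(th), y = c(r1, rep(8, 7)) * sin(th), z = 0))
  }
  r_base <- pore_radius_profile(mk(8), c(0, 0), 1, axis_xy = c(0, 0))$radius
  r_in <- pore_radius_profile(mk(5), c(0, 0), 1, axis_xy = c(0, 0))$radius
  expect_lt(r_in, r_base)
})
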
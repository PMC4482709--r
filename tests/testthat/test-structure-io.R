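pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     record = "ATOM") {
  sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, resname, chain, resseq, x, y, z, 1, 0)
}

test_that("read_pdb echoes fields of a small single-model file", {
  txt <- c(pdb_line(1, "CA", "ALA", "A", 1, 1.234, -2.5, 3.75),
           pdb_line(2, "CB", "ALA", "A", 1, 0.001, 10.25, -9.875))
  s <- read_pdb(txt)
  expect_s3_class(s, "mol_structure")
  expect_equal(n_atoms(s), 2L)
  expect_equal(s$atoms$name, c("CA", "CB"))
  expect_equal(coords(s)[1, ], c(x = 1.234, y = -2.5, z = 3.75))
  expect_equal(coords(s)[2, ], c(x = 0.001, y = 10.25, z = -9.875))
  expect_equal(s$atoms$element, c("C", "C"))
})

test_that("multi-model files become trajectories; mismatches are errors", {
  model <- function(m, natoms, dx = 0) {
    c(sprintf("MODEL     %4d", m),
      vapply(seq_len(natoms), function(i) {
        pdb_line(i, "CA", "GLY", "A", i, i + dx, 0, 0)
      }, character(1L)),
      "ENDMDL")
  }
  traj <- read_pdb(c(model(1, 5), model(2, 5, 1), model(3, 5, 2)),
                   multi = TRUE)
  expect_s3_class(traj, "mol_trajectory")
  expect_equal(n_frames(traj), 3L)
  expect_equal(n_atoms(traj), 5L)
  expect_equal(frame_coords(traj, 3)[, 1], 1:5 + 2)

  expect_error(read_pdb(c(model(1, 5), model(2, 4)), multi = TRUE),
               "topology mismatch")
})

test_that("malformed records report the offending line number", {
  good <- pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3)
  bad <- "ATOM      2  CB ALA A   1      bad.coord   0.000   0.000"
  expect_error(read_pdb(c(good, bad)), "line 2")
  expect_error(read_pdb(c(good, "ATOM   3 CA")), "line 2")
})

test_that("PDB round trip preserves identities exactly and coordinates to 1e-3", {
  s <- random_structure(25, seed = 11)
  s$atoms$hetatm <- s$atoms$resname == "HOH"
  s2 <- read_pdb(write_pdb(s))
  expect_identical(s2$atoms[, c("name", "resname", "chain", "resseq", "hetatm")],
                   s$atoms[, c("name", "resname", "chain", "resseq", "hetatm")])
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3 + 1e-9)

  traj <- mol_trajectory(s, list(coords(s), coords(s) + 0.5))
  txt <- write_pdb(traj)
  expect_equal(length(gregexpr("MODEL", txt)[[1L]]), 2L)
  traj2 <- read_pdb(txt, multi = TRUE)
  expect_equal(n_frames(traj2), 2L)
  expect_lt(max(abs(traj2$frames - traj$frames)), 1e-3 + 1e-9)
})

test_that("out-of-range coordinates refuse to serialise", {
  s <- mol_structure(data.frame(name = "CA", resname = "ALA", chain = "A",
                                resseq = 1L, x = 123456.0, y = 0, z = 0))
  expect_error(write_pdb(s), "not representable")
})

test_that("altloc B conformers are dropped on read", {
  lineA <- paste0(substr(pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3), 1, 16),
                  "A", substr(pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3), 18, 66))
  lineB <- paste0(substr(pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9), 1, 16),
                  "B", substr(pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9), 18, 66))
  s <- read_pdb(c(lineA, lineB))
  expect_equal(n_atoms(s), 1L)
  expect_equal(coords(s)[1, "x"], c(x = 1))
})

test_that("selection resolution matches brute-force filtering on random structures", {
  set.seed(202)
  for (rep in 1:10) {
    s <- random_structure(40)
    chain <- sample(c(NA, "A", "B"), 1)
    name <- sample(c(NA, "CA", "OE1"), 1)
    rs <- if (runif(1) < 0.5) sample(1:40, 10) else NULL
    sel <- atom_selection(chain = if (is.na(chain)) NULL else chain,
                          resseq = rs,
                          name = if (is.na(name)) NULL else name)
    expect_identical(resolve_selection(s, sel),
                     oracle_select(s, chain = if (is.na(chain)) NULL else chain,
                                   resseq = rs,
                                   name = if (is.na(name)) NULL else name))
  }
})

test_that("selection unions concatenate disjoint ranges without duplicates", {
  b <- make_helical_bundle(3, 10)
  u <- sel_union(atom_selection(resseq = 1:5), atom_selection(resseq = 21:25))
  got <- resolve_selection(b, u)
  want <- sort(c(oracle_select(b, resseq = 1:5), oracle_select(b, resseq = 21:25)))
  expect_identical(got, want)
  expect_false(any(duplicated(got)))
  # overlapping union still has no duplicates
  u2 <- sel_union(atom_selection(resseq = 1:8), atom_selection(resseq = 5:12))
  expect_identical(resolve_selection(b, u2), oracle_select(b, resseq = 1:12))
})

test_that("unknown chain warns and yields an empty result", {
  b <- make_helical_bundle(2, 5)
  expect_warning(idx <- resolve_selection(b, atom_selection(chain = "Z")),
                 "unknown chain")
  expect_length(idx, 0L)
  expect_silent(idx2 <- resolve_selection(b, atom_selection(resname = "XXX")))
  expect_length(idx2, 0L)
})

test_that("DX files round trip and reject non-finite voxels", {
  g <- list(origin = c(-1, 0, 2), spacing = 0.5, dims = c(3L, 4L, 5L),
            values = array(runif(60), dim = c(3, 4, 5)))
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  g2 <- read_dx(f)
  expect_equal(g2$dims, g$dims)
  expect_equal(g2$origin, g$origin)
  expect_lt(max(abs(g2$values - g$values)), 1e-6)

  zero <- list(origin = c(0, 0, 0), spacing = 1, dims = c(2L, 2L, 2L),
               values = array(0, dim = c(2, 2, 2)))
  write_dx(zero, f)
  expect_equal(sum(abs(read_dx(f)$values)), 0)

  g$values[1] <- NaN
  expect_error(write_dx(g, f), "non-finite")
})
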
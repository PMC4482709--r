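# Independent oracles, deliberately written as plain brute force so they
# share no code path with the package implementation.

# brute-force selection: filter every atom through the clause predicates
oracle_select <- function(structure, chain = NULL, resseq = NULL,
                          resname = NULL, name = NULL) {
  a <- structure$atoms
  out <- integer(0)
  for (i in seq_len(nrow(a))) {
    ok <- TRUE
    if (!is.null(chain) && !(a$chain[i] %in% chain)) ok <- FALSE
    if (!is.null(resseq) && !(a$resseq[i] %in% resseq)) ok <- FALSE
    if (!is.null(resname) && !(a$resname[i] %in% resname)) ok <- FALSE
    if (!is.null(name) && !(a$name[i] %in% name)) ok <- FALSE
    if (ok) out <- c(out, i)
  }
  out
}

# naive per-frame RMSD loop
oracle_rmsd <- function(xyz, ref) {
  s <- 0
  for (i in seq_len(nrow(xyz))) {
    s <- s + sum((xyz[i, ] - ref[i, ])^2)
  }
  sqrt(s / nrow(xyz))
}

# axis-angle rotation grid (step degrees); returns the minimum RMSD over
# the grid with the optimal translation applied for each rotation
oracle_grid_min_rmsd <- function(mobile, target, step = 10) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(target, 2L, ct)
  best <- Inf
  for (theta in seq(0, 180, by = step)) {
    for (phi in seq(0, 350, by = step)) {
      ax <- c(sin(theta * pi / 180) * cos(phi * pi / 180),
              sin(theta * pi / 180) * sin(phi * pi / 180),
              cos(theta * pi / 180))
      for (ang in seq(0, 350, by = step)) {
        R <- rotation_axis_angle(ax, ang)
        d <- Y - X %*% t(R)
        r <- sqrt(mean(rowSums(d^2)))
        if (r < best) best <- r
      }
    }
  }
  best
}

# union-find connectivity: are any low-slab and high-slab points connected
# through pairwise links of length <= cutoff?
oracle_spanning <- function(xyz, slab_low, slab_high, cutoff) {
  n <- nrow(xyz)
  if (!n) return(FALSE)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sqrt(sum((xyz[i, ] - xyz[j, ]) ^ 2)) <= cutoff) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  lo <- which(xyz[, 3L] >= slab_low[1L] & xyz[, 3L] <= slab_low[2L])
  hi <- which(xyz[, 3L] >= slab_high[1L] & xyz[, 3L] <= slab_high[2L])
  if (!length(lo) || !length(hi)) return(FALSE)
  roots_lo <- unique(vapply(lo, find, integer(1L)))
  roots_hi <- unique(vapply(hi, find, integer(1L)))
  length(intersect(roots_lo, roots_hi)) > 0L
}

# dense radial scan: largest r (in steps of `step`) such that a sphere at
# the axis point clears every atom by its vdW radius
oracle_pore_radius <- function(p, xyz, rv, bound, step = 0.005) {
  r <- 0
  repeat {
    nxt <- r + step
    if (nxt > bound) return(bound)
    ok <- TRUE
    for (i in seq_len(nrow(xyz))) {
      if (sqrt(sum((p - xyz[i, ])^2)) < nxt + rv[i]) {
        ok <- FALSE
        break
      }
    }
    if (!ok) return(r)
    r <- nxt
  }
}

# four-point dihedral via the acos/sign formulation (distinct from the
# package's atan2 version)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosv))) * 180 / pi
  s <- sum(n1 * b3)
  if (s < 0) -ang else ang
}

# direct normalised-covariance DCCM computed with explicit loops
oracle_dccm <- function(frames_array, idx) {
  F <- dim(frames_array)[3L]
  N <- length(idx)
  D <- array(0, dim = c(N, 3L, F))
  for (f in seq_len(F)) D[, , f] <- frames_array[idx, , f]
  mean_pos <- apply(D, c(1L, 2L), mean)
  for (f in seq_len(F)) D[, , f] <- D[, , f] - mean_pos
  C <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      num <- 0; vi <- 0; vj <- 0
      for (f in seq_len(F)) {
        num <- num + sum(D[i, , f] * D[j, , f])
        vi <- vi + sum(D[i, , f]^2)
        vj <- vj + sum(D[j, , f]^2)
      }
      C[i, j] <- num / sqrt(vi * vj)
    }
  }
  C
}

random_structure <- function(n = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mol_structure(data.frame(
    name = sample(c("CA", "CB", "N", "O", "OE1"), n, replace = TRUE),
    resname = sample(c("ALA", "GLU", "ARG", "HOH"), n, replace = TRUE),
    chain = sample(c("A", "B"), n, replace = TRUE),
    resseq = seq_len(n),
    x = round(runif(n, -50, 50), 3),
    y = round(runif(n, -50, 50), 3),
    z = round(runif(n, -50, 50), 3),
    stringsAsFactors = FALSE
  ))
}
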
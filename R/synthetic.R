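# Synthetic generators with planted ground truth. Every downstream analysis
# (superposition, DCCM, contacts, hydration, grafting) is exercised
# closed-loop against what these functions plant, so no structure downloads
# are needed for testing.

#' Build an idealised C-alpha helical bundle
#'
#' Places `n_helices` ideal alpha-helical C-alpha traces (rise 1.5 A per
#' residue, 100 degrees twist, C-alpha radius 2.3 A) with vertical axes on a
#' circle of radius `bundle_radius`. Residues are numbered contiguously
#' across helices on one chain, emulating a seven-transmembrane fold at toy
#' scale.
#'
#' @param n_helices Number of helices (>= 2).
#' @param residues_per_helix Residues in each helix.
#' @param bundle_radius Radius of the circle of helix axes, Angstrom.
#' @param helix_radius C-alpha helix radius, Angstrom.
#' @param rise Rise per residue, Angstrom.
#' @param twist Twist per residue, degrees.
#' @param chain Chain id.
#' @return A `mol_structure` of C-alpha atoms with attribute `helix_ranges`:
#'   a named list of inclusive residue-number ranges `c(first, last)`, one
#'   per helix.
#' @export
#' @examples
#' b <- make_helical_bundle(7, 20)
#' n_atoms(b)            # 140
#' attr(b, "helix_ranges")$H1
make_helical_bundle <- function(n_helices = 7L, residues_per_helix = 20L,
                                bundle_radius = 12, helix_radius = 2.3,
                                rise = 1.5, twist = 100, chain = "A") {
  stopifnot(n_helices >= 2L, residues_per_helix >= 1L)
  atoms <- vector("list", n_helices)
  ranges <- vector("list", n_helices)
  for (h in seq_len(n_helices)) {
    phi <- 2 * pi * (h - 1L) / n_helices
    cx <- bundle_radius * cos(phi)
    cy <- bundle_radius * sin(phi)
    k <- seq_len(residues_per_helix) - 1L
    theta <- (k * twist * pi / 180) + phi
    first <- (h - 1L) * residues_per_helix + 1L
    atoms[[h]] <- data.frame(
      name = "CA", resname = "ALA", chain = chain,
      resseq = first + k,
      x = cx + helix_radius * cos(theta),
      y = cy + helix_radius * sin(theta),
      z = k * rise,
      stringsAsFactors = FALSE
    )
    ranges[[h]] <- c(first, first + residues_per_helix - 1L)
  }
  names(ranges) <- paste0("H", seq_len(n_helices))
  s <- mol_structure(do.call(rbind, atoms))
  attr(s, "helix_ranges") <- ranges
  s
}

# Helix-level correlation matrix from a block table; validated PSD.
helix_correlation_matrix <- function(n_helices, blocks) {
  G <- diag(n_helices)
  if (!is.null(blocks) && nrow(blocks)) {
    stopifnot(all(c("helix_a", "helix_b", "rho") %in% names(blocks)))
    if (any(blocks$rho < -1 | blocks$rho > 1)) {
      stop("block rho must lie in [-1, 1]")
    }
    for (i in seq_len(nrow(blocks))) {
      a <- blocks$helix_a[i]; b <- blocks$helix_b[i]
      G[a, b] <- G[b, a] <- blocks$rho[i]
    }
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("planted helix correlation specification is not positive semi-definite")
  }
  G
}

#' Simulate a trajectory with planted inter-helix displacement correlations
#'
#' Per frame and per Cartesian component, each helix receives a latent
#' zero-mean Gaussian factor; the factors of different helices carry the
#' planted correlation `rho` from `blocks`, and every residue of a helix
#' shares its helix factor (scaled by `fluctuation_sd`). The same `rho` is
#' applied to x, y and z (isotropic), so the theoretical dynamic
#' cross-correlation between residues of two paired helices equals `rho`
#' exactly. An optional random rigid-body transform (uniform axis, uniform
#' angle up to the stated maximum; uniform direction and magnitude for the
#' translation) is applied to each whole frame to exercise superposition.
#'
#' @param bundle A structure from [make_helical_bundle()] (or any structure
#'   with a `helix_ranges` attribute / supplied `helix_ranges`).
#' @param n_frames Number of frames.
#' @param fluctuation_sd Per-component displacement standard deviation, A.
#' @param blocks Data frame with columns `helix_a`, `helix_b`, `rho`
#'   (helix indices; rho in [-1, 1]); NULL for independent helices.
#' @param rigid_noise Length-2 numeric `c(max_rotation_deg, max_translation_A)`.
#' @param helix_fluctuation_scale Optional per-helix multiplier on
#'   `fluctuation_sd` (length = number of helices); lets some helices be
#'   quasi-static, as the stable core helices a trajectory is fitted on.
#'   Correlations are scale-free, so the planted DCCM is unchanged.
#' @param helix_coherence Fraction (0..1] of displacement variance carried by
#'   the shared helix factor; 1 (default) makes the planted block correlation
#'   the exact theoretical DCCM value.
#' @param frame_interval_ns Frame interval, ns.
#' @param helix_ranges Override for the bundle's helix ranges.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return List with `trajectory` (`mol_trajectory`), `correlation` (planted
#'   theoretical residue-residue DCCM), `helix_correlation` (helix-level
#'   matrix), and `helix_ranges`.
#' @export
simulate_correlated_trajectory <- function(bundle, n_frames = 1000L,
                                           fluctuation_sd = 0.5,
                                           blocks = NULL,
                                           rigid_noise = c(0, 0),
                                           helix_fluctuation_scale = NULL,
                                           helix_coherence = 1,
                                           frame_interval_ns = 0.1,
                                           helix_ranges = NULL,
                                           seed = NULL) {
  ranges <- helix_ranges %||% attr(bundle, "helix_ranges")
  if (is.null(ranges)) stop("bundle carries no helix_ranges attribute")
  stopifnot(helix_coherence > 0, helix_coherence <= 1,
            length(rigid_noise) == 2L, all(rigid_noise >= 0))
  H <- length(ranges)
  G <- helix_correlation_matrix(H, blocks)
  hscale <- helix_fluctuation_scale %||% rep(1, H)
  stopifnot(length(hscale) == H, all(hscale > 0))

  a <- bundle$atoms
  helix_of <- rep(NA_integer_, nrow(a))
  for (h in seq_len(H)) {
    helix_of[a$resseq >= ranges[[h]][1L] & a$resseq <= ranges[[h]][2L]] <- h
  }
  if (anyNA(helix_of)) stop("some residues fall outside all helix ranges")
  N <- nrow(a)
  lam <- helix_coherence

  eg <- eigen(G, symmetric = TRUE)
  A_mix <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), H)

  base <- coords(bundle)
  frames <- with_seed(seed, {
    disp <- array(0, dim = c(n_frames, N, 3L))
    for (comp in 1:3) {
      fac <- matrix(stats::rnorm(n_frames * H), n_frames, H) %*% t(A_mix)
      d <- sqrt(lam) * fac[, helix_of, drop = FALSE]
      if (lam < 1) {
        d <- d + sqrt(1 - lam) * matrix(stats::rnorm(n_frames * N),
                                        n_frames, N)
      }
      disp[, , comp] <- fluctuation_sd *
        sweep(d, 2L, hscale[helix_of], "*")
    }
    fr <- array(0, dim = c(N, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      xyz <- base + cbind(disp[f, , 1L], disp[f, , 2L], disp[f, , 3L])
      if (any(rigid_noise > 0)) {
        ax <- stats::rnorm(3L)
        ang <- stats::runif(1L, 0, rigid_noise[1L])
        R <- rotation_axis_angle(ax, ang)
        tdir <- stats::rnorm(3L)
        tr <- unit_vec(tdir) * stats::runif(1L, 0, rigid_noise[2L])
        xyz <- xyz %*% t(R) + matrix(tr, N, 3L, byrow = TRUE)
      }
      fr[, , f] <- xyz
    }
    fr
  })

  corr_true <- lam * G[helix_of, helix_of]
  diag(corr_true) <- 1
  list(trajectory = mol_trajectory(bundle, frames,
                                   frame_interval_ns = frame_interval_ns),
       correlation = corr_true,
       helix_correlation = G,
       helix_ranges = ranges)
}

#' A straight water wire between two z-slabs
#'
#' Convenience generator of equally spaced points on a vertical line,
#' suitable as the `wire` argument of [make_water_scene()].
#'
#' @param x,y Lateral position of the wire, Angstrom.
#' @param z_from,z_to End-point z coordinates (should lie inside the two
#'   slabs used downstream).
#' @param spacing Target point spacing, Angstrom (<= the downstream H-bond
#'   cutoff; 2.8 mimics a hydrogen-bonded water chain).
#' @return A k x 3 matrix of points.
#' @export
straight_wire <- function(x = 0, y = 0, z_from, z_to, spacing = 2.8) {
  len <- abs(z_to - z_from)
  k <- max(2L, ceiling(len / spacing) + 1L)
  z <- seq(z_from, z_to, length.out = k)
  cbind(x = rep(x, k), y = rep(y, k), z = z)
}

#' Generate a water scene with optional planted spanning wire
#'
#' Background water oxygens are placed uniformly at random each frame with a
#' Poisson-distributed count of mean `background_density x box volume`. In
#' the frames listed in `wire_frames` the fixed `wire` points are added,
#' giving a continuous chain linking the two z-slabs. Because the trajectory
#' container requires a fixed topology, unoccupied water slots in a frame
#' are parked at a remote point far outside any useful grid or slab; they
#' are counted as outside-grid by [water_density()] and can never join a
#' slab-to-slab path.
#'
#' @param box_origin,box_lengths Axis-aligned box, Angstrom.
#' @param background_density Molecules per cubic Angstrom.
#' @param n_frames Number of frames.
#' @param wire Optional k x 3 matrix of wire points (see [straight_wire()]);
#'   consecutive points must be within `wire_spacing_max` and all points
#'   inside the box.
#' @param wire_frames Integer frame indices (1-based) in which the wire is
#'   present.
#' @param slab_low,slab_high Disjoint z-intervals `c(zmin, zmax)` defining
#'   the two membrane sides.
#' @param frame_interval_ns Frame interval, ns.
#' @param wire_spacing_max Validation bound on consecutive wire spacing
#'   (default 3.5, the downstream hydrogen-bond cutoff).
#' @param seed Integer seed.
#' @return List with `trajectory` (water oxygens, chain "W"), `spanning`
#'   (planted logical per frame), `n_background` (active background waters
#'   per frame), `wire_frames`, `box_origin`, `box_lengths`, `slab_low`,
#'   `slab_high`.
#' @export
make_water_scene <- function(box_origin = c(0, 0, 0),
                             box_lengths = c(40, 40, 40),
                             background_density = 0.001,
                             n_frames = 20L,
                             wire = NULL, wire_frames = integer(0),
                             slab_low = NULL, slab_high = NULL,
                             frame_interval_ns = 0.1,
                             wire_spacing_max = 3.5,
                             seed = NULL) {
  vol <- prod(box_lengths)
  if (background_density * vol >= 1e5) {
    stop("background density x box volume must stay below 1e5 molecules")
  }
  if (!is.null(slab_low) && !is.null(slab_high)) {
    if (max(slab_low) > min(slab_high) && max(slab_high) > min(slab_low)) {
      if (!(slab_low[2L] < slab_high[1L] || slab_high[2L] < slab_low[1L])) {
        stop("slab_low and slab_high must be disjoint z-intervals")
      }
    }
  }
  nw <- 0L
  if (!is.null(wire)) {
    wire <- as.matrix(wire)
    nw <- nrow(wire)
    lo <- box_origin; hi <- box_origin + box_lengths
    inside <- wire[, 1L] >= lo[1L] & wire[, 1L] <= hi[1L] &
      wire[, 2L] >= lo[2L] & wire[, 2L] <= hi[2L] &
      wire[, 3L] >= lo[3L] & wire[, 3L] <= hi[3L]
    if (!all(inside)) stop("wire point outside the box")
    if (nw > 1L) {
      gaps <- sqrt(rowSums((wire[-1L, , drop = FALSE] -
                              wire[-nw, , drop = FALSE])^2))
      if (any(gaps > wire_spacing_max)) {
        stop("consecutive wire points exceed the spacing bound of ",
             wire_spacing_max, " A")
      }
    }
  }
  wire_frames <- sort(unique(as.integer(wire_frames)))
  if (length(wire_frames) && (min(wire_frames) < 1L ||
                              max(wire_frames) > n_frames)) {
    stop("wire_frames outside 1..n_frames")
  }
  has_wire <- seq_len(n_frames) %in% wire_frames & nw > 0L

  out <- with_seed(seed, {
    n_bg <- stats::rpois(n_frames, background_density * vol)
    slots <- max(c(n_bg + ifelse(has_wire, nw, 0L), 1L))
    park <- c(3000, 3000, 3000)
    frames <- array(rep(park, each = slots), dim = c(slots, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      pts <- matrix(stats::runif(3L * n_bg[f]), ncol = 3L)
      pts <- sweep(sweep(pts, 2L, box_lengths, "*"), 2L, box_origin, "+")
      if (has_wire[f]) pts <- rbind(wire, pts)
      if (nrow(pts)) frames[seq_len(nrow(pts)), , f] <- pts
    }
    list(n_bg = n_bg, frames = frames, slots = slots)
  })

  topo <- mol_structure(data.frame(
    name = "O", resname = "HOH", chain = "W",
    resseq = seq_len(out$slots),
    x = 0, y = 0, z = 0, hetatm = TRUE,
    stringsAsFactors = FALSE
  ))
  list(trajectory = mol_trajectory(topo, out$frames,
                                   frame_interval_ns = frame_interval_ns),
       spanning = has_wire,
       n_background = out$n_bg,
       wire_frames = wire_frames,
       box_origin = box_origin, box_lengths = box_lengths,
       slab_low = slab_low, slab_high = slab_high)
}

#' Simulate a two-state (formed/broken) contact distance series
#'
#' A symmetric two-state Markov chain (per-frame persistence probability
#' `p_stay`) emits `d_formed` or `d_broken` plus Gaussian noise, emulating a
#' hydrogen bond or salt bridge that is disrupted and reformed during a
#' simulation.
#'
#' @param n_frames Number of frames.
#' @param d_formed,d_broken State mean distances, Angstrom
#'   (`d_formed < d_broken`).
#' @param p_stay Probability of keeping the current state each frame,
#'   in (0, 1]; `p_stay = 1` freezes the initial state.
#' @param noise_sd Gaussian noise standard deviation, Angstrom.
#' @param start_formed Initial state (default formed).
#' @param frame_interval_ns Frame interval, ns.
#' @param label Series label.
#' @param seed Integer seed.
#' @return List with `series` (a `distance_series` data frame: `frame`,
#'   `time_ns`, `distance`), `states` (planted logical, TRUE = formed) and
#'   `occupancy` (planted formed fraction).
#' @export
simulate_two_state_distance <- function(n_frames = 1000L,
                                        d_formed = 2.8, d_broken = 8.0,
                                        p_stay = 0.98, noise_sd = 0.2,
                                        start_formed = TRUE,
                                        frame_interval_ns = 0.1,
                                        label = "two-state contact",
                                        seed = NULL) {
  if (!(d_formed < d_broken)) stop("d_formed must be < d_broken")
  if (!(p_stay > 0 && p_stay <= 1)) stop("p_stay must lie in (0, 1]")
  res <- with_seed(seed, {
    flips <- if (n_frames > 1L) stats::runif(n_frames - 1L) > p_stay else logical(0)
    parity <- cumsum(c(FALSE, flips)) %% 2L
    states <- if (start_formed) parity == 0L else parity == 1L
    noise <- stats::rnorm(n_frames, 0, noise_sd)
    list(states = states, noise = noise)
  })
  states <- res$states
  d <- ifelse(states, d_formed, d_broken) + res$noise
  series <- distance_series_df(seq_len(n_frames), frame_interval_ns,
                               pmax(d, 0), label)
  list(series = series, states = states, occupancy = mean(states))
}

#' Build a toy retinal-like fragment in trans or cis conformation
#'
#' A planar lysine-retinal stand-in: main-chain anchors (N, CA, C, O), a
#' lysine-like linker (CB..NZ), a polyene tail (C15..C7) and a six-membered
#' ring (C1..C6) standing in for the beta-ionone ring. The tail torsion
#' about the C13=C14 bond (atoms C12-C13-C14-C15) is 180 degrees for
#' `"trans"` and 0 for `"cis"`; all bond lengths lie in 1.4-1.6 Angstrom.
#' The anchor atom set (main chain + ring) is identical between the two
#' conformations, mirroring how a 13-cis fragment is superimposed onto an
#' all-trans one before transplanting.
#'
#' @param conformation `"trans"` or `"cis"`.
#' @return A `mol_structure` with attributes `anchors` (anchor atom names)
#'   and `tail_dihedral_atoms` (the four tail-torsion atom names).
#' @export
make_toy_retinal <- function(conformation = c("trans", "cis")) {
  conformation <- match.arg(conformation)
  tail_torsion <- if (conformation == "trans") 180 else 0

  # NeRF placement: new atom bonded to p3, with given p4-p3-p2 angle and
  # p4-p3-p2-p1 torsion (degrees).
  place <- function(p1, p2, p3, bond, angle, torsion) {
    ang <- angle * pi / 180
    tor <- torsion * pi / 180
    b2 <- unit_vec(p3 - p2)
    n <- unit_vec(cross3(unit_vec(p2 - p1), b2))
    m <- cross3(n, b2)
    d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
           bond * sin(ang) * sin(tor))
    p3 + d[1L] * b2 + d[2L] * m + d[3L] * n
  }

  pos <- list()
  pos$N <- c(0, 0, 0)
  pos$CA <- c(1.47, 0, 0)
  pos$C <- pos$CA + 1.52 * c(-cos(111 * pi / 180), sin(111 * pi / 180), 0)
  pos$O <- place(pos$N, pos$CA, pos$C, 1.43, 121, 0)
  pos$CB <- place(pos$C, pos$N, pos$CA, 1.53, 110, 180)
  pos$CG <- place(pos$N, pos$CA, pos$CB, 1.53, 112, 180)
  pos$CD <- place(pos$CA, pos$CB, pos$CG, 1.53, 112, 180)
  pos$CE <- place(pos$CB, pos$CG, pos$CD, 1.53, 112, 180)
  pos$NZ <- place(pos$CG, pos$CD, pos$CE, 1.47, 112, 180)
  pos$C15 <- place(pos$CD, pos$CE, pos$NZ, 1.45, 120, 180)
  pos$C14 <- place(pos$CE, pos$NZ, pos$C15, 1.45, 120, 180)
  pos$C13 <- place(pos$NZ, pos$C15, pos$C14, 1.45, 120, 180)
  pos$C12 <- place(pos$C15, pos$C14, pos$C13, 1.45, 120, tail_torsion)
  pos$C11 <- place(pos$C14, pos$C13, pos$C12, 1.45, 120, 180)
  pos$C10 <- place(pos$C13, pos$C12, pos$C11, 1.45, 120, 180)
  pos$C9 <- place(pos$C12, pos$C11, pos$C10, 1.45, 120, 180)
  pos$C8 <- place(pos$C11, pos$C10, pos$C9, 1.45, 120, 180)
  pos$C7 <- place(pos$C10, pos$C9, pos$C8, 1.45, 120, 180)
  pos$C1 <- place(pos$C9, pos$C8, pos$C7, 1.50, 120, 180)

  # regular hexagon (side 1.5) in the local molecular plane, fused at C1
  nrm <- unit_vec(cross3(pos$C8 - pos$C7, pos$C1 - pos$C7))
  center <- pos$C1 + 1.5 * unit_vec(pos$C1 - pos$C7)
  e1 <- unit_vec(pos$C1 - center)
  e2 <- cross3(nrm, e1)
  for (k in 1:5) {
    th <- k * pi / 3
    pos[[paste0("C", k + 1L)]] <- center + 1.5 * (cos(th) * e1 + sin(th) * e2)
  }

  nm <- names(pos)
  xyz <- do.call(rbind, pos)
  s <- mol_structure(data.frame(
    name = nm, resname = "LYR", chain = "A", resseq = 1L,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    hetatm = TRUE, stringsAsFactors = FALSE
  ))
  attr(s, "anchors") <- c("C", "O", "N", "CA", paste0("C", 1:6))
  attr(s, "tail_dihedral_atoms") <- c("C12", "C13", "C14", "C15")
  attr(s, "conformation") <- conformation
  s
}
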
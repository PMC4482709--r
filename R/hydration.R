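# Water-occupancy density maps, iso-level contouring, membrane-spanning
# water-wire detection and pore-radius profiles. The wire criterion
# operationalises "formation of a water-mediated hydrogen-bond network
# connecting the two membrane sides": a graph on water oxygens with edges
# at the heavy-atom H-bond cutoff, spanning iff the two z-slabs are
# connected. No periodic-boundary handling: trajectories are assumed
# wrapped with the channel contiguous.

#' Grid specification for density maps
#'
#' @param origin Grid origin (corner), Angstrom.
#' @param spacing Isotropic voxel edge, Angstrom (> 0; default 1.0).
#' @param dims Integer voxel counts `c(nx, ny, nz)`.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(origin, spacing = 1.0, dims) {
  stopifnot(spacing > 0, length(dims) == 3L, all(dims >= 1L))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims)), class = "grid_spec")
}

#' Water-oxygen occupancy density map
#'
#' Each selected water oxygen increments its containing voxel in every
#' frame. The voxel value is `count / (voxel_volume x n_frames x
#' frame_interval_ns)`, i.e. molecules per cubic Angstrom per nanosecond --
#' the probability-density unit channel water maps are contoured in
#' (e.g. at 0.0015). The conservation identity
#' `sum(values) x voxel_volume x total_ns == total in-grid counts`
#' holds exactly. Waters outside the grid are tallied, not binned.
#'
#' @param trajectory A `mol_trajectory` (superposed if the protein frame is
#'   the reference of interest).
#' @param grid A [grid_spec()].
#' @param water_sel Selection of water oxygens (default [water_selection()]).
#' @param per_frame_average If TRUE, report the VolMap-style per-frame mean
#'   occupancy density (molecules per cubic Angstrom) instead of the
#'   per-nanosecond probability density.
#' @return An object of class `density_grid`: `origin`, `spacing`, `dims`,
#'   `values` (3D array), `counts` (raw voxel counts), `n_outside`,
#'   `n_frames`, `frame_interval_ns`, `unit`.
#' @export
water_density <- function(trajectory, grid,
                          water_sel = water_selection(),
                          per_frame_average = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  F <- n_frames(trajectory)
  if (F < 1L) stop("trajectory has no frames")
  idx <- resolve_selection(trajectory, water_sel)
  dims <- grid$dims
  counts <- integer(prod(dims))
  n_outside <- 0L
  for (f in seq_len(F)) {
    xyz <- frame_coords(trajectory, f)[idx, , drop = FALSE]
    v <- floor(sweep(xyz, 2L, grid$origin) / grid$spacing)
    ok <- v[, 1L] >= 0 & v[, 1L] < dims[1L] &
      v[, 2L] >= 0 & v[, 2L] < dims[2L] &
      v[, 3L] >= 0 & v[, 3L] < dims[3L]
    n_outside <- n_outside + sum(!ok)
    if (any(ok)) {
      lin <- 1L + v[ok, 1L] + dims[1L] * (v[ok, 2L] + dims[2L] * v[ok, 3L])
      tab <- tabulate(lin, nbins = length(counts))
      counts <- counts + tab
    }
  }
  vol <- grid$spacing^3
  denom <- if (per_frame_average) vol * F else
    vol * F * trajectory$frame_interval_ns
  values <- array(counts / denom, dim = dims)
  structure(list(origin = grid$origin, spacing = grid$spacing, dims = dims,
                 values = values, counts = array(counts, dim = dims),
                 n_outside = n_outside, n_frames = F,
                 frame_interval_ns = trajectory$frame_interval_ns,
                 unit = if (per_frame_average) "molecules A^-3"
                        else "molecules A^-3 ns^-1"),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %dx%dx%d voxels @ %.2f A, max %.4g %s, %d outside\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$spacing,
              max(x$values), x$unit, x$n_outside))
  invisible(x)
}

#' Iso-level voxel mask of a density grid
#'
#' @param grid A `density_grid`.
#' @param level Contour level (>= 0) in the grid's unit; the conventional
#'   channel-hydration contour is 0.0015 molecules per cubic Angstrom per
#'   nanosecond.
#' @return List with `mask` (logical array, value >= level) and `count`.
#' @export
iso_level_mask <- function(grid, level = 0.0015) {
  stopifnot(level >= 0)
  mask <- grid$values >= level
  list(mask = mask, count = sum(mask))
}

# BFS shortest path from any source to any sink over an adjacency list;
# neighbours visited in increasing index order so ties break towards the
# smallest atom-id sequence. Returns integer path or NULL.
bfs_span_path <- function(nbr, sources, sinks) {
  n <- length(nbr)
  if (!length(sources) || !length(sinks)) return(NULL)
  is_sink <- rep(FALSE, n)
  is_sink[sinks] <- TRUE
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  queue <- sort(sources)
  visited[queue] <- TRUE
  head <- 1L
  while (head <= length(queue)) {
    u <- queue[head]
    if (is_sink[u]) {
      path <- u
      while (!is.na(parent[u])) {
        u <- parent[u]
        path <- c(u, path)
      }
      return(path)
    }
    head <- head + 1L
    for (v in nbr[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  NULL
}

#' Membrane-spanning water-wire test on one frame
#'
#' Builds a graph whose nodes are the supplied points (water oxygens, and
#' optionally protein polar heavy atoms) with edges between pairs within
#' `cutoff`, and asks whether any node inside the lower z-slab is connected
#' to any node inside the upper z-slab. The returned path is a
#' breadth-first shortest path (fewest nodes, ties towards smaller ids).
#'
#' @param xyz n x 3 coordinate matrix of candidate network nodes.
#' @param slab_low,slab_high Disjoint z-intervals `c(zmin, zmax)`.
#' @param cutoff Hydrogen-bond heavy-atom cutoff, Angstrom (default 3.5).
#' @param ids Optional node ids reported in the path (default 1..n).
#' @return List with `spanning` (logical) and `path` (integer ids, empty if
#'   not spanning).
#' @export
water_wire <- function(xyz, slab_low, slab_high, cutoff = 3.5,
                       ids = NULL) {
  stopifnot(cutoff > 0, length(slab_low) == 2L, length(slab_high) == 2L)
  if (!(slab_low[2L] < slab_high[1L] || slab_high[2L] < slab_low[1L])) {
    stop("slabs must be disjoint along z")
  }
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  ids <- ids %||% seq_len(n)
  if (!n) return(list(spanning = FALSE, path = integer(0)))
  z <- xyz[, 3L]
  sources <- which(z >= slab_low[1L] & z <= slab_low[2L])
  sinks <- which(z >= slab_high[1L] & z <= slab_high[2L])
  if (!length(sources) || !length(sinks)) {
    return(list(spanning = FALSE, path = integer(0)))
  }
  d2 <- outer(rowSums(xyz^2), rep(1, n)) +
    outer(rep(1, n), rowSums(xyz^2)) - 2 * xyz %*% t(xyz)
  adj <- d2 <= cutoff^2
  diag(adj) <- FALSE
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ]))
  path <- bfs_span_path(nbr, sources, sinks)
  if (is.null(path)) {
    list(spanning = FALSE, path = integer(0))
  } else {
    list(spanning = TRUE, path = ids[path])
  }
}

#' Per-frame water-wire report for a trajectory
#'
#' Applies [water_wire()] to every frame and summarises the spanning
#' fraction -- the closed-loop analogue of asking in what fraction of a run
#' a continuous water pathway linked the two membrane sides.
#'
#' @param trajectory A `mol_trajectory`.
#' @param slab_low,slab_high Disjoint z-intervals, Angstrom.
#' @param cutoff H-bond cutoff, Angstrom.
#' @param node_sel Selection of network nodes (default water oxygens; union
#'   in protein polar atoms to allow protein-mediated links).
#' @return An object of class `wire_report`: `per_frame` (data frame
#'   `frame`, `spanning`, `path_length`), `paths` (list of id vectors),
#'   `spanning_fraction`, `cutoff`, `slab_low`, `slab_high`.
#' @export
wire_fraction <- function(trajectory, slab_low, slab_high, cutoff = 3.5,
                          node_sel = water_selection()) {
  idx <- resolve_selection(trajectory, node_sel)
  F <- n_frames(trajectory)
  spanning <- logical(F)
  paths <- vector("list", F)
  for (f in seq_len(F)) {
    xyz <- frame_coords(trajectory, f)[idx, , drop = FALSE]
    res <- water_wire(xyz, slab_low, slab_high, cutoff, ids = idx)
    spanning[f] <- res$spanning
    paths[[f]] <- res$path
  }
  structure(list(per_frame = data.frame(
    frame = seq_len(F), spanning = spanning,
    path_length = lengths(paths)),
    paths = paths,
    spanning_fraction = mean(spanning),
    cutoff = cutoff, slab_low = slab_low, slab_high = slab_high),
    class = "wire_report")
}

#' @export
print.wire_report <- function(x, ...) {
  cat(sprintf("<wire_report> spanning in %d/%d frames (fraction %.3f), cutoff %.2f A\n",
              sum(x$per_frame$spanning), nrow(x$per_frame),
              x$spanning_fraction, x$cutoff))
  invisible(x)
}

# Bondi van der Waals radii (Angstrom) for the elements this package meets.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75)

vdw_radius <- function(element, default = 1.70) {
  r <- BONDI_RADII[toupper(element)]
  r[is.na(r)] <- default
  unname(r)
}

#' Pore-radius profile along a vertical axis
#'
#' For each z-slice, the largest radius of a sphere centred on the axis
#' point that clears every atom (centre distance >= radius + atom van der
#' Waals radius). With the centre fixed on the axis this maximum has the
#' closed form `min_i(|p - x_i| - vdw_i)`, evaluated exactly. Slices where
#' no atom constrains the sphere within `search_radius` are reported at the
#' search bound and flagged.
#'
#' @param structure A `mol_structure` (e.g. a time-averaged snapshot).
#' @param z_range `c(zmin, zmax)` of the profile, Angstrom.
#' @param slice_thickness Spacing of slice centres, Angstrom.
#' @param axis_xy Lateral `c(x, y)` position of the vertical axis; default
#'   the geometric centre of `lining_sel`.
#' @param lining_sel Selection used for the default axis (default all atoms).
#' @param atom_sel Selection of the atoms that constrain the pore (default
#'   all atoms; typically the protein, excluding waters).
#' @param search_radius Upper bound on reported radii, Angstrom.
#' @return A data frame of class `pore_profile`: `z`, `radius`, `flagged`.
#' @export
pore_radius_profile <- function(structure, z_range, slice_thickness = 1.0,
                                axis_xy = NULL, lining_sel = NULL,
                                atom_sel = NULL, search_radius = 10) {
  stopifnot(slice_thickness > 0, search_radius > 0)
  if (is.null(axis_xy)) {
    idx <- resolve_selection(structure, lining_sel)
    axis_xy <- if (length(idx)) {
      colMeans(coords(structure)[idx, 1:2, drop = FALSE])
    } else {
      c(0, 0)
    }
  }
  zs <- seq(z_range[1L], z_range[2L], by = slice_thickness)
  aidx <- resolve_selection(structure, atom_sel)
  xyz <- coords(structure)[aidx, , drop = FALSE]
  rv <- if (nrow(xyz)) vdw_radius(structure$atoms$element[aidx]) else numeric(0)
  radius <- numeric(length(zs))
  flagged <- logical(length(zs))
  for (i in seq_along(zs)) {
    p <- c(axis_xy, zs[i])
    if (!nrow(xyz)) {
      radius[i] <- search_radius
      flagged[i] <- TRUE
      next
    }
    d <- sqrt(rowSums(sweep(xyz, 2L, p)^2))
    r <- min(d - rv)
    if (r > search_radius) {
      radius[i] <- search_radius
      flagged[i] <- TRUE
    } else {
      radius[i] <- max(0, r)
    }
  }
  out <- data.frame(z = zs, radius = radius, flagged = flagged)
  attr(out, "axis_xy") <- axis_xy
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' @export
plot.pore_profile <- function(x, ...) {
  plot(x$z, x$radius, type = "l", xlab = "z (Å)",
       ylab = "pore radius (Å)", ...)
  if (any(x$flagged)) {
    points(x$z[x$flagged], x$radius[x$flagged], pch = 4)
  }
  invisible(x)
}
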
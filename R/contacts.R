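# Residue-pair distance series and hydrogen-bond / salt-bridge occupancy
# with hysteresis-based disruption/reformation event detection, the kind of
# quantity plotted as "distance between Glu122 and His173 over 150 ns".

distance_series_df <- function(frames, frame_interval_ns, distance, label) {
  out <- data.frame(frame = frames,
                    time_ns = (frames - 1L) * frame_interval_ns,
                    distance = distance)
  attr(out, "label") <- label
  class(out) <- c("distance_series", "data.frame")
  out
}

#' @export
plot.distance_series <- function(x, ...) {
  plot(x$time_ns, x$distance, type = "l", xlab = "time (ns)",
       ylab = "distance (Å)", main = attr(x, "label"), ...)
  invisible(x)
}

#' Residue-pair specification
#'
#' Default salt-bridge/H-bond atom groups follow the field's convention:
#' carboxylate oxygens (OE1/OE2, OD1/OD2) against guanidinium/amine/imidazole
#' nitrogens, compared by minimum heavy-atom distance.
#'
#' @param label Pair label, e.g. `"Glu121-Arg307"`.
#' @param group_a,group_b `atom_selection`s; both must be non-empty on the
#'   analysed topology.
#' @param mode `"min"` (minimum heavy-atom cross distance) or `"atom"`
#'   (both groups must resolve to exactly one atom).
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(label, group_a, group_b, mode = c("min", "atom")) {
  stopifnot(inherits(group_a, "atom_selection"),
            inherits(group_b, "atom_selection"))
  structure(list(label = label, group_a = group_a, group_b = group_b,
                 mode = match.arg(mode)),
            class = "pair_spec")
}

#' Distance time series for a residue pair
#'
#' Per frame, the minimum distance over all heavy-atom pairs between the two
#' groups (`mode = "min"`), or the single named atom-pair distance
#' (`mode = "atom"`). Hydrogens are excluded in `"min"` mode.
#'
#' @param trajectory A `mol_trajectory`.
#' @param pair A [pair_spec()].
#' @return A `distance_series` data frame: `frame`, `time_ns`, `distance`.
#' @export
distance_series <- function(trajectory, pair) {
  stopifnot(inherits(pair, "pair_spec"))
  topo <- trajectory$topology
  ia <- resolve_selection(topo, pair$group_a)
  ib <- resolve_selection(topo, pair$group_b)
  if (pair$mode == "min") {
    heavy <- which(topo$atoms$element != "H")
    ia <- intersect(ia, heavy)
    ib <- intersect(ib, heavy)
  }
  if (!length(ia) || !length(ib)) {
    stop("empty atom group for pair '", pair$label, "'")
  }
  if (pair$mode == "atom" && (length(ia) != 1L || length(ib) != 1L)) {
    stop("mode 'atom' needs exactly one atom per group for pair '",
         pair$label, "'")
  }
  F <- n_frames(trajectory)
  vals <- vapply(seq_len(F), function(f) {
    xyz <- frame_coords(trajectory, f)
    A <- xyz[ia, , drop = FALSE]
    B <- xyz[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    sqrt(max(0, min(d2)))
  }, numeric(1L))
  distance_series_df(seq_len(F), trajectory$frame_interval_ns, vals,
                     pair$label)
}

#' Hysteresis contact states and disruption/reformation events
#'
#' Two-threshold state machine: a formed contact breaks when the distance
#' exceeds `break_cutoff`; a broken one reforms when the distance drops to
#' `formed_cutoff` or below (ties count as formed). The band
#' `formed_cutoff <= break_cutoff` suppresses cutoff chatter so events are
#' countable. The initial state is formed iff the first distance is
#' <= `formed_cutoff`.
#'
#' @param series A `distance_series`, or a numeric distance vector.
#' @param formed_cutoff,break_cutoff Thresholds in Angstrom with
#'   `formed_cutoff <= break_cutoff`. Defaults are the hydrogen-bond
#'   settings (3.5/4.5); use 4.0/5.0 for salt bridges.
#' @return An object of class `contact_events`: list with `states` (logical
#'   per frame, TRUE = formed), `occupancy` (formed fraction), `events`
#'   (data frame `type` in disruption/reformation, `frame`).
#' @export
contact_states <- function(series, formed_cutoff = 3.5, break_cutoff = 4.5) {
  if (!(formed_cutoff <= break_cutoff)) {
    stop("formed_cutoff must be <= break_cutoff (hysteresis band)")
  }
  d <- if (is.data.frame(series)) series$distance else as.numeric(series)
  n <- length(d)
  if (!n) stop("empty distance series")
  states <- logical(n)
  st <- d[1L] <= formed_cutoff
  states[1L] <- st
  type <- character(0)
  at <- integer(0)
  for (f in seq_len(n)[-1L]) {
    if (st && d[f] > break_cutoff) {
      st <- FALSE
      type <- c(type, "disruption"); at <- c(at, f)
    } else if (!st && d[f] <= formed_cutoff) {
      st <- TRUE
      type <- c(type, "reformation"); at <- c(at, f)
    }
    states[f] <- st
  }
  structure(list(states = states, occupancy = mean(states),
                 events = data.frame(type = type, frame = at,
                                     stringsAsFactors = FALSE)),
            class = "contact_events")
}

#' @export
print.contact_events <- function(x, ...) {
  cat(sprintf("<contact_events> occupancy %.3f over %d frames, %d event(s)\n",
              x$occupancy, length(x$states), nrow(x$events)))
  invisible(x)
}

#' Replay an event list into per-frame states
#'
#' Reconstructs the state vector from the initial state and the event list;
#' by construction it reproduces `contact_states()$states` exactly.
#'
#' @param events A `contact_events` object.
#' @param n Number of frames (default: length of the stored state vector).
#' @return Logical vector of states.
#' @export
replay_events <- function(events, n = length(events$states)) {
  st <- if (nrow(events$events)) {
    events$events$type[1L] == "disruption"
  } else {
    isTRUE(events$states[1L])
  }
  out <- logical(n)
  ev <- events$events
  j <- 1L
  for (f in seq_len(n)) {
    while (j <= nrow(ev) && ev$frame[j] == f) {
      st <- ev$type[j] == "reformation"
      j <- j + 1L
    }
    out[f] <- st
  }
  out
}

#' Heavy-atom hydrogen-bond presence test
#'
#' True iff the donor-acceptor heavy-atom distance is at or below the
#' cutoff (ties count as bonded). When an angle criterion is requested but
#' no hydrogen coordinates are supplied, the test falls back to
#' distance-only with a warning.
#'
#' @param donor,acceptor Numeric 3-vectors (heavy-atom coordinates).
#' @param cutoff Heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param hydrogen Optional hydrogen coordinate (3-vector) for the angle
#'   criterion.
#' @param angle_cutoff Optional minimum donor-H-acceptor angle, degrees.
#' @return Logical scalar.
#' @export
hbond_present <- function(donor, acceptor, cutoff = 3.5,
                          hydrogen = NULL, angle_cutoff = NULL) {
  d <- vnorm(as.numeric(acceptor) - as.numeric(donor))
  ok <- d <= cutoff
  if (!is.null(angle_cutoff)) {
    if (is.null(hydrogen)) {
      warning("angle criterion requested without hydrogens; using distance only")
    } else if (ok) {
      v1 <- unit_vec(as.numeric(donor) - as.numeric(hydrogen))
      v2 <- unit_vec(as.numeric(acceptor) - as.numeric(hydrogen))
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
      ok <- ang >= angle_cutoff
    }
  }
  ok
}

#' Default salt-bridge atom-name groups
#'
#' Standard heavy-atom groups for acidic and basic side chains: Glu/Asp
#' carboxylate oxygens vs Arg/Lys/His nitrogens.
#'
#' @param resname Three-letter residue code (GLU, ASP, ARG, LYS, HIS).
#' @return Character vector of atom names.
#' @export
salt_bridge_atoms <- function(resname) {
  switch(toupper(resname),
         GLU = c("OE1", "OE2"),
         ASP = c("OD1", "OD2"),
         ARG = c("NH1", "NH2", "NE"),
         LYS = "NZ",
         HIS = c("ND1", "NE2"),
         ASN = c("OD1", "ND2"),
         stop("no default side-chain group for residue ", resname))
}
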
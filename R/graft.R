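# Anchored rigid-fragment grafting: the computational replacement of an
# all-trans chromophore by its 13-cis isomer. The donor fragment is
# superimposed on name-defined anchor pairs (main-chain atoms plus the
# ring), transplanted as a rigid body, and checked for steric clashes.
# Energy minimisation after replacement belongs to an MD engine and is
# deliberately replaced by clash reporting here.

anchor_coords <- function(structure, names_wanted, indices = NULL, what) {
  a <- structure$atoms
  idx <- indices %||% seq_len(nrow(a))
  out <- matrix(NA_real_, length(names_wanted), 3L)
  for (i in seq_along(names_wanted)) {
    hit <- idx[a$name[idx] == names_wanted[i]]
    if (length(hit) == 0L) {
      stop("graft error: anchor atom '", names_wanted[i],
           "' not found in ", what)
    }
    if (length(hit) > 1L) {
      stop("graft error: anchor atom '", names_wanted[i],
           "' is not unique in ", what)
    }
    out[i, ] <- as.numeric(a[hit, c("x", "y", "z")])
  }
  out
}

#' Graft specification
#'
#' @param donor Donor fragment `mol_structure` (e.g. the cis chromophore).
#' @param target_selection `atom_selection` identifying the acceptor atoms
#'   to be replaced (e.g. the bound trans chromophore).
#' @param anchor_pairs Data frame with columns `donor` and `acceptor`
#'   (atom names, >= 3 rows); correspondence is by name, as in main-chain
#'   (C, O, N, CA) plus ring-atom anchoring.
#' @param weights Optional per-anchor fit weights (default uniform: ring
#'   atoms weigh the same as main-chain atoms).
#' @return A `graft_spec` list.
#' @export
graft_spec <- function(donor, target_selection, anchor_pairs,
                       weights = NULL) {
  stopifnot(inherits(donor, "mol_structure"),
            inherits(target_selection, "atom_selection"))
  anchor_pairs <- as.data.frame(anchor_pairs, stringsAsFactors = FALSE)
  if (!all(c("donor", "acceptor") %in% names(anchor_pairs)) ||
      nrow(anchor_pairs) < 3L) {
    stop("anchor_pairs needs columns 'donor', 'acceptor' and >= 3 rows")
  }
  structure(list(donor = donor, target_selection = target_selection,
                 anchor_pairs = anchor_pairs, weights = weights),
            class = "graft_spec")
}

#' Graft a donor fragment onto an acceptor structure
#'
#' Superimposes the donor's anchor atoms onto the acceptor's (Kabsch fit on
#' the name-defined anchor pairs), applies the resulting rigid transform to
#' the whole donor fragment, and substitutes it for the acceptor's target
#' atoms at their position in the atom order. Being rigid, the transplant
#' preserves every donor internal distance; untouched acceptor atoms are
#' unchanged. Grafted atoms inherit the chain and residue number of the
#' replaced fragment.
#'
#' @param acceptor The acceptor `mol_structure`.
#' @param spec A [graft_spec()].
#' @param clash_cutoff Heavy-atom clash distance for the report, Angstrom.
#' @param anchor_rmsd_warn Warn (not fail) if the anchor fit RMSD exceeds
#'   this sanity bound, Angstrom.
#' @return List with `structure` (grafted `mol_structure`) and `report`
#'   (class `graft_report`: `anchor_rmsd`, `replaced_atom_count`, `clashes`,
#'   `grafted_indices`).
#' @export
graft_fragment <- function(acceptor, spec, clash_cutoff = 2.0,
                           anchor_rmsd_warn = 2.0) {
  stopifnot(inherits(spec, "graft_spec"))
  target_idx <- resolve_selection(acceptor, spec$target_selection)
  if (!length(target_idx)) stop("graft error: target selection is empty")
  don_xyz <- anchor_coords(spec$donor, spec$anchor_pairs$donor,
                           what = "donor fragment")
  acc_xyz <- anchor_coords(acceptor, spec$anchor_pairs$acceptor,
                           indices = target_idx, what = "acceptor target")
  fit <- kabsch_fit(don_xyz, acc_xyz, spec$weights)
  if (fit$rmsd > anchor_rmsd_warn) {
    warning(sprintf("anchor RMSD %.3f A exceeds sanity bound %.2f A",
                    fit$rmsd, anchor_rmsd_warn))
  }
  donor <- apply_transform(fit, spec$donor)

  acc_atoms <- acceptor$atoms
  don_atoms <- donor$atoms
  don_atoms$chain <- acc_atoms$chain[target_idx[1L]]
  don_atoms$resseq <- acc_atoms$resseq[target_idx[1L]]
  don_atoms$hetatm <- TRUE

  keep <- setdiff(seq_len(nrow(acc_atoms)), target_idx)
  insert_at <- sum(keep < target_idx[1L])
  before <- acc_atoms[keep[seq_len(insert_at)], , drop = FALSE]
  after <- if (insert_at < length(keep)) {
    acc_atoms[keep[(insert_at + 1L):length(keep)], , drop = FALSE]
  } else {
    acc_atoms[0L, , drop = FALSE]
  }
  new_atoms <- rbind(before, don_atoms, after)
  new_atoms$serial <- seq_len(nrow(new_atoms))
  out <- mol_structure(new_atoms, metadata = acceptor$metadata)
  grafted_idx <- insert_at + seq_len(nrow(don_atoms))

  # atoms covalently adjacent to the removed fragment's anchors stay bonded
  # to the grafted anchors: exclude those junction pairs from the clash list
  env_idx <- setdiff(seq_len(nrow(new_atoms)), grafted_idx)
  exclude <- NULL
  if (length(env_idx)) {
    env_xyz <- coords(out)[env_idx, , drop = FALSE]
    near_anchor <- rep(FALSE, length(env_idx))
    for (r in seq_len(nrow(acc_xyz))) {
      dd <- sqrt(rowSums(sweep(env_xyz, 2L, acc_xyz[r, ])^2))
      near_anchor <- near_anchor | dd <= 1.8
    }
    junction_env <- env_idx[near_anchor]
    anchor_grafted <- grafted_idx[new_atoms$name[grafted_idx] %in%
                                    spec$anchor_pairs$donor]
    if (length(junction_env) && length(anchor_grafted)) {
      exclude <- expand.grid(grafted = anchor_grafted,
                             environment = junction_env)
    }
  }
  clashes <- clash_check(out, grafted_idx, cutoff = clash_cutoff,
                         exclude_pairs = exclude)
  report <- structure(list(anchor_rmsd = fit$rmsd,
                           replaced_atom_count = length(target_idx),
                           clashes = clashes,
                           grafted_indices = grafted_idx),
                      class = "graft_report")
  list(structure = out, report = report)
}

#' @export
print.graft_report <- function(x, ...) {
  cat(sprintf("<graft_report> anchor RMSD %.4f A, %d atoms replaced, %d clash(es)\n",
              x$anchor_rmsd, x$replaced_atom_count, nrow(x$clashes)))
  invisible(x)
}

#' Steric clash scan between a grafted atom set and its environment
#'
#' Lists all heavy-atom pairs (one grafted, one environment) closer than
#' `cutoff`, optionally excluding pairs bonded through the anchor junction.
#'
#' @param structure A `mol_structure`.
#' @param grafted_idx Integer indices of the grafted atoms.
#' @param cutoff Clash distance, Angstrom (> 0).
#' @param exclude_pairs Optional data frame with columns `grafted`,
#'   `environment` of index pairs to ignore.
#' @return Data frame `grafted`, `environment`, `distance`, ordered by
#'   distance.
#' @export
clash_check <- function(structure, grafted_idx, cutoff = 2.0,
                        exclude_pairs = NULL) {
  stopifnot(cutoff > 0)
  a <- structure$atoms
  heavy <- a$element != "H"
  g <- intersect(grafted_idx, which(heavy))
  e <- setdiff(which(heavy), grafted_idx)
  if (!length(g) || !length(e)) {
    return(data.frame(grafted = integer(0), environment = integer(0),
                      distance = numeric(0)))
  }
  gx <- coords(structure)[g, , drop = FALSE]
  ex <- coords(structure)[e, , drop = FALSE]
  d2 <- outer(rowSums(gx^2), rep(1, length(e))) +
    outer(rep(1, length(g)), rowSums(ex^2)) - 2 * gx %*% t(ex)
  hits <- which(d2 < cutoff^2, arr.ind = TRUE)
  out <- data.frame(grafted = g[hits[, 1L]],
                    environment = e[hits[, 2L]],
                    distance = sqrt(pmax(d2[hits], 0)))
  if (!is.null(exclude_pairs) && nrow(out)) {
    key_out <- paste(out$grafted, out$environment)
    key_ex <- paste(exclude_pairs$grafted, exclude_pairs$environment)
    out <- out[!(key_out %in% key_ex), , drop = FALSE]
  }
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
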
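# Core containers: a single-model structure, a fixed-topology trajectory,
# and atom selections resolving to deterministic index sets.

ATOM_COLUMNS <- c("serial", "name", "resname", "chain", "resseq",
                  "x", "y", "z", "occupancy", "bfactor", "element", "hetatm")

# Infer an element symbol from a PDB atom name: strip leading digits and
# spaces, take the first alphabetic character. Good enough for the protein,
# water and toy-fragment atoms this package handles; two-letter metals are
# not resolved (documented limitation).
infer_element <- function(name) {
  stripped <- sub("^[0-9 ]+", "", name)
  toupper(substr(stripped, 1L, 1L))
}

#' Construct a molecular structure
#'
#' A structure is an ordered atom table plus a free-form metadata list. Atom
#' identity is `(chain, resseq, name)` and must be unique within one model.
#'
#' @param atoms Data frame with columns `name`, `resname`, `chain`, `resseq`,
#'   `x`, `y`, `z` and optionally `serial`, `occupancy`, `bfactor`,
#'   `element`, `hetatm`. Missing optional columns are filled with defaults.
#' @param metadata Named list of header information.
#' @param validate Check invariants (finite coordinates, unique identities).
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, metadata = list(), validate = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, n)
  if (is.null(atoms$bfactor)) atoms$bfactor <- rep(0, n)
  if (is.null(atoms$hetatm)) atoms$hetatm <- rep(FALSE, n)
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$name)
  missing_cols <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$serial <- as.integer(atoms$serial)
  atoms <- atoms[, ATOM_COLUMNS]
  rownames(atoms) <- NULL
  if (validate && n > 0L) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("non-finite atom coordinates")
    }
    key <- paste(atoms$chain, atoms$resseq, atoms$name, sep = "|")
    if (anyDuplicated(key)) {
      stop("duplicate atom identity (chain, resseq, name): ",
           key[which(duplicated(key))[1L]])
    }
  }
  structure(list(atoms = atoms, metadata = metadata),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<mol_structure> %d atoms, %d residues, chains: %s\n",
              nrow(a),
              length(unique(paste(a$chain, a$resseq))),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure or trajectory topology
#' @param x A `mol_structure` or `mol_trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "mol_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Get or set atom coordinates of a structure
#' @param x A `mol_structure`.
#' @return An n x 3 numeric matrix (columns x, y, z).
#' @export
coords <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value An n x 3 numeric matrix.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nrow(x$atoms), ncol(value) == 3L)
  x$atoms$x <- value[, 1L]
  x$atoms$y <- value[, 2L]
  x$atoms$z <- value[, 3L]
  x
}

#' Construct a trajectory
#'
#' Fixed topology plus ordered coordinate frames with a constant frame
#' interval. Frames are stored as an `n_atoms` x 3 x `n_frames` array.
#'
#' @param topology A `mol_structure` providing atom identities.
#' @param frames Either an n x 3 x F array or a list of n x 3 matrices.
#' @param frame_interval_ns Time between consecutive frames, ns; must be > 0.
#' @return An object of class `mol_trajectory`.
#' @export
mol_trajectory <- function(topology, frames, frame_interval_ns = 0.1) {
  stopifnot(inherits(topology, "mol_structure"))
  if (is.list(frames)) {
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(nrow(frames[[1L]]), 3L, length(frames)))
  }
  if (length(dim(frames)) != 3L || dim(frames)[2L] != 3L) {
    stop("frames must be an n_atoms x 3 x n_frames array")
  }
  if (dim(frames)[1L] != n_atoms(topology)) {
    stop("topology mismatch: frames carry ", dim(frames)[1L],
         " atoms but topology has ", n_atoms(topology))
  }
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0) {
    stop("frame_interval_ns must be > 0")
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval_ns = frame_interval_ns),
            class = "mol_trajectory")
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("<mol_trajectory> %d atoms x %d frames, dt = %g ns (%g ns total)\n",
              n_atoms(x), n_frames(x), x$frame_interval_ns,
              n_frames(x) * x$frame_interval_ns))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `mol_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) {
  dim(trajectory$frames)[3L]
}

#' Coordinates of one trajectory frame
#' @param trajectory A `mol_trajectory`.
#' @param i Frame index (1-based).
#' @return An n x 3 matrix.
#' @export
frame_coords <- function(trajectory, i) {
  matrix(trajectory$frames[, , i], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Structure snapshot of one trajectory frame
#' @inheritParams frame_coords
#' @return A `mol_structure` with the topology's identities and frame `i`
#'   coordinates.
#' @export
frame_structure <- function(trajectory, i) {
  s <- trajectory$topology
  coords(s) <- frame_coords(trajectory, i)
  s
}

#' Time-averaged structure of a trajectory
#' @param trajectory A `mol_trajectory`.
#' @return A `mol_structure` whose coordinates are the per-atom mean over
#'   frames.
#' @export
average_structure <- function(trajectory) {
  s <- trajectory$topology
  coords(s) <- apply(trajectory$frames, c(1L, 2L), mean)
  s
}

#' Atom selection
#'
#' One selection is a disjunction of clauses; each clause is a conjunction of
#' optional predicates on chain id, residue number (inclusive; pass any
#' integer vector, e.g. `5:20` or `c(1:10, 30:40)`), residue name, and atom
#' name. `NULL` predicates match everything. Combine clauses with
#' [sel_union()].
#'
#' @param chain Character vector of chain ids, or NULL.
#' @param resseq Integer vector of residue numbers, or NULL.
#' @param resname Character vector of residue names, or NULL.
#' @param name Character vector of atom names, or NULL.
#' @return An object of class `atom_selection`.
#' @export
#' @examples
#' sel <- atom_selection(chain = "A", resseq = 1:10, name = "CA")
atom_selection <- function(chain = NULL, resseq = NULL,
                           resname = NULL, name = NULL) {
  clause <- list(chain = chain,
                 resseq = if (is.null(resseq)) NULL else as.integer(resseq),
                 resname = resname, name = name)
  structure(list(clauses = list(clause)), class = "atom_selection")
}

#' Union of atom selections
#' @param ... `atom_selection` objects.
#' @return An `atom_selection` matching atoms matched by any argument.
#' @export
sel_union <- function(...) {
  sels <- list(...)
  stopifnot(all(vapply(sels, inherits, logical(1L), "atom_selection")))
  structure(list(clauses = unlist(lapply(sels, `[[`, "clauses"),
                                  recursive = FALSE)),
            class = "atom_selection")
}

#' A selection for standard water residues
#'
#' Matches the residue names used by common PDB/CHARMM dialects
#' (HOH, TIP3, WAT, SOL), oxygen atoms only by default.
#'
#' @param oxygens_only Keep only atoms named O/OH2/OW.
#' @return An `atom_selection`.
#' @export
water_selection <- function(oxygens_only = TRUE) {
  atom_selection(resname = c("HOH", "TIP3", "WAT", "SOL"),
                 name = if (oxygens_only) c("O", "OH2", "OW") else NULL)
}

#' Resolve a selection against a structure
#'
#' Deterministic: indices are returned in atom order and resolving twice
#' yields identical results. A clause naming a chain id absent from the
#' structure emits a warning and contributes no atoms (not an error).
#'
#' @param structure A `mol_structure` (or `mol_trajectory`, resolved on its
#'   topology).
#' @param selection An `atom_selection`, or NULL for all atoms.
#' @return Sorted integer vector of atom indices (possibly empty).
#' @export
resolve_selection <- function(structure, selection = NULL) {
  if (inherits(structure, "mol_trajectory")) structure <- structure$topology
  a <- structure$atoms
  if (is.null(selection)) return(seq_len(nrow(a)))
  stopifnot(inherits(selection, "atom_selection"))
  hit <- rep(FALSE, nrow(a))
  for (cl in selection$clauses) {
    if (!is.null(cl$chain)) {
      unknown <- setdiff(cl$chain, unique(a$chain))
      if (length(unknown)) {
        warning("selection references unknown chain id(s): ",
                paste(unknown, collapse = ", "))
      }
    }
    m <- rep(TRUE, nrow(a))
    if (!is.null(cl$chain)) m <- m & a$chain %in% cl$chain
    if (!is.null(cl$resseq)) m <- m & a$resseq %in% cl$resseq
    if (!is.null(cl$resname)) m <- m & a$resname %in% cl$resname
    if (!is.null(cl$name)) m <- m & a$name %in% cl$name
    hit <- hit | m
  }
  which(hit)
}
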
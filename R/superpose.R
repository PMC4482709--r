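# Least-squares rigid-body superposition (Kabsch) and RMSD quantities.
# Fit and measure selections are independent: trajectories are typically
# fitted on one helix set (e.g. TM1-7 or TM3-5 of a rhodopsin) and measured
# on another (a single helix, a residue, all C-alpha atoms).

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the (weighted)
#' RMSD of `R x + t` against the target. Reflections are excluded by
#' sign-correcting the smallest singular vector, so the rotation determinant
#' is +1 even for (near-)planar point clouds.
#'
#' @param mobile,target n x 3 coordinate matrices (n >= 3, non-collinear).
#' @param weights Optional non-negative per-point weights (default uniform).
#' @return A `rigid_transform`: list with `rotation` (3x3), `translation`
#'   (length 3) and `rmsd` (post-fit weighted RMSD, Angstrom).
#' @export
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' R <- rotation_axis_angle(c(1, 2, 3), 40)
#' fit <- kabsch_fit(p, p %*% t(R) + 5)
#' fit$rmsd   # ~0
kabsch_fit <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  n <- nrow(mobile)
  if (n != nrow(target)) stop("mobile and target must have equal lengths")
  if (n < 3L) stop("degenerate fit: need at least 3 point pairs")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(target, 2L, ct)
  sv_m <- svd(X * sqrt(w))$d
  if (sv_m[2L] < 1e-8 * max(sv_m[1L], 1e-12)) {
    stop("degenerate fit: point set is collinear")
  }
  H <- crossprod(X * w, Y)
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  if (s == 0) s <- 1
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  tr <- ct - as.numeric(R %*% cm)
  dev <- Y - X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums(dev * dev)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, |t| = %.3f A, fit RMSD %.4g A\n",
              ang, vnorm(x$translation), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform`.
#' @param x An n x 3 matrix, `mol_structure`, or `mol_trajectory`.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(transform, x) {
  R <- transform$rotation
  tr <- transform$translation
  tx <- function(m) sweep(m %*% t(R), 2L, tr, "+")
  if (is.matrix(x)) return(tx(x))
  if (inherits(x, "mol_structure")) {
    coords(x) <- tx(coords(x))
    return(x)
  }
  if (inherits(x, "mol_trajectory")) {
    for (f in seq_len(n_frames(x))) x$frames[, , f] <- tx(frame_coords(x, f))
    return(x)
  }
  stop("unsupported input to apply_transform")
}

#' Superpose every trajectory frame onto a reference selection
#'
#' Each frame receives its own Kabsch fit of the `fit_selection` atoms onto
#' the corresponding reference atoms; the resulting transform is applied to
#' the whole frame. Frame order and interval are preserved.
#'
#' @param trajectory A `mol_trajectory`.
#' @param reference A `mol_structure` (e.g. the crystal structure the runs
#'   started from, or [average_structure()]).
#' @param fit_selection An `atom_selection` resolving to >= 3 atoms in both
#'   topologies (NULL = all atoms).
#' @param weights Optional per-atom fit weights.
#' @return The superposed `mol_trajectory`, with attribute `fit_rmsd`
#'   (per-frame fit-selection RMSD after fitting).
#' @export
superpose_trajectory <- function(trajectory, reference, fit_selection = NULL,
                                 weights = NULL) {
  it <- resolve_selection(trajectory, fit_selection)
  ir <- resolve_selection(reference, fit_selection)
  if (length(it) < 3L || length(ir) < 3L) {
    stop("fit selection resolves to fewer than 3 atoms")
  }
  if (length(it) != length(ir)) {
    stop("fit selection resolves to different atom counts in trajectory (",
         length(it), ") and reference (", length(ir), ")")
  }
  ref <- coords(reference)[ir, , drop = FALSE]
  fit_rmsd <- numeric(n_frames(trajectory))
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- frame_coords(trajectory, f)
    fit <- kabsch_fit(xyz[it, , drop = FALSE], ref, weights)
    trajectory$frames[, , f] <- apply_transform(fit, xyz)
    fit_rmsd[f] <- fit$rmsd
  }
  attr(trajectory, "fit_rmsd") <- fit_rmsd
  trajectory
}

#' Per-frame RMSD of a selection against a reference
#'
#' The trajectory is assumed already superposed (see
#' [superpose_trajectory()]); no fitting is performed here.
#'
#' @param trajectory A (superposed) `mol_trajectory`.
#' @param reference A `mol_structure`.
#' @param measure_selection Non-empty `atom_selection` (NULL = all atoms).
#' @param label Series label.
#' @return A data frame of class `rmsd_series`: `frame`, `time_ns`, `rmsd`.
#' @export
rmsd_series <- function(trajectory, reference, measure_selection = NULL,
                        label = "rmsd") {
  it <- resolve_selection(trajectory, measure_selection)
  ir <- resolve_selection(reference, measure_selection)
  if (!length(it) || !length(ir)) stop("empty measure selection")
  if (length(it) != length(ir)) {
    stop("measure selection resolves to different atom counts")
  }
  ref <- coords(reference)[ir, , drop = FALSE]
  F <- n_frames(trajectory)
  vals <- vapply(seq_len(F), function(f) {
    d <- frame_coords(trajectory, f)[it, , drop = FALSE] - ref
    sqrt(mean(rowSums(d * d)))
  }, numeric(1L))
  out <- data.frame(frame = seq_len(F),
                    time_ns = (seq_len(F) - 1L) * trajectory$frame_interval_ns,
                    rmsd = vals)
  attr(out, "label") <- label
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' @export
plot.rmsd_series <- function(x, ...) {
  plot(x$time_ns, x$rmsd, type = "l", xlab = "time (ns)",
       ylab = "RMSD (Å)", main = attr(x, "label"), ...)
  invisible(x)
}

#' Per-residue time-averaged RMSD profile
#'
#' For each residue with selected atoms, the root of the mean squared
#' deviation pooled over all frames and the residue's selected atoms -- an
#' RMSD profile along the sequence. Residues with no selected atoms are
#' excluded with a message.
#'
#' @param trajectory A (superposed) `mol_trajectory`.
#' @param reference A `mol_structure` with matching selected atoms.
#' @param selection Atom selection grouped per residue (default: C-alpha
#'   atoms).
#' @return A data frame of class `per_residue_rmsd`: `chain`, `resseq`,
#'   `rmsd`.
#' @export
per_residue_rmsd <- function(trajectory, reference,
                             selection = atom_selection(name = "CA")) {
  it <- resolve_selection(trajectory, selection)
  ir <- resolve_selection(reference, selection)
  if (!length(it)) stop("selection resolves to no atoms")
  if (length(it) != length(ir)) {
    stop("selection resolves to different atom counts in trajectory and reference")
  }
  atoms <- trajectory$topology$atoms[it, , drop = FALSE]
  ref <- coords(reference)[ir, , drop = FALSE]
  F <- n_frames(trajectory)
  sqsum <- numeric(length(it))
  for (f in seq_len(F)) {
    d <- frame_coords(trajectory, f)[it, , drop = FALSE] - ref
    sqsum <- sqsum + rowSums(d * d)
  }
  msd_atom <- sqsum / F
  grp <- paste(atoms$chain, atoms$resseq, sep = "|")
  grp <- factor(grp, levels = unique(grp))
  msd_res <- tapply(msd_atom, grp, mean)
  first <- !duplicated(grp)
  out <- data.frame(chain = atoms$chain[first],
                    resseq = atoms$resseq[first],
                    rmsd = sqrt(as.numeric(msd_res)))
  class(out) <- c("per_residue_rmsd", "data.frame")
  out
}
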
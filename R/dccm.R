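# Dynamic cross-correlation matrix (DCCM) of C-alpha displacement vectors
# and region-pair reports of correlated / anticorrelated helix motions.
# Standard normalised-covariance form:
#   C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>),
# displacements taken relative to the trajectory-mean position by default
# (the crystal-referenced variant is available via `reference`).

#' Dynamic cross-correlation matrix of selected atoms
#'
#' The trajectory should already be superposed on the intended fit
#' selection (commonly a stable helix subset, distinct from the analysed
#' atoms). Zero-variance atoms get NA rows/columns (diagonal excepted) with
#' a warning.
#'
#' @param trajectory A (superposed) `mol_trajectory` with >= 2 frames.
#' @param selection Atom selection (default: C-alpha atoms).
#' @param reference Optional `mol_structure`; when given, displacements are
#'   taken relative to it instead of the trajectory mean.
#' @return An object of class `correlation_matrix`: the N x N matrix with
#'   `chain:resseq` dimnames and a `labels` attribute (data frame `chain`,
#'   `resseq`).
#' @export
dccm <- function(trajectory, selection = atom_selection(name = "CA"),
                 reference = NULL) {
  idx <- resolve_selection(trajectory, selection)
  if (!length(idx)) stop("selection resolves to no atoms")
  F <- n_frames(trajectory)
  if (F < 2L) stop("need at least 2 frames")
  N <- length(idx)
  X <- trajectory$frames[idx, 1L, , drop = FALSE]
  dim(X) <- c(N, F)
  Y <- trajectory$frames[idx, 2L, , drop = FALSE]
  dim(Y) <- c(N, F)
  Z <- trajectory$frames[idx, 3L, , drop = FALSE]
  dim(Z) <- c(N, F)
  if (is.null(reference)) {
    X <- X - rowMeans(X)
    Y <- Y - rowMeans(Y)
    Z <- Z - rowMeans(Z)
  } else {
    iref <- resolve_selection(reference, selection)
    if (length(iref) != N) stop("reference selection mismatch")
    rxyz <- coords(reference)[iref, , drop = FALSE]
    X <- X - rxyz[, 1L]
    Y <- Y - rxyz[, 2L]
    Z <- Z - rxyz[, 3L]
  }
  S <- (tcrossprod(X) + tcrossprod(Y) + tcrossprod(Z)) / F
  v <- diag(S)
  zero_var <- v <= 0 | !is.finite(v)
  if (any(zero_var)) {
    warning(sum(zero_var), " selected atom(s) have zero displacement variance;",
            " their correlations are NA")
    v[zero_var] <- NA_real_
  }
  C <- S / sqrt(outer(v, v))
  C <- pmax(pmin(C, 1), -1)
  diag(C) <- 1
  atoms <- trajectory$topology$atoms[idx, , drop = FALSE]
  labels <- data.frame(chain = atoms$chain, resseq = atoms$resseq,
                       stringsAsFactors = FALSE)
  nm <- paste0(labels$chain, ":", labels$resseq)
  dimnames(C) <- list(nm, nm)
  attr(C, "labels") <- labels
  class(C) <- c("correlation_matrix", "matrix", "array")
  C
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d, range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.correlation_matrix <- function(x, ...) {
  n <- nrow(x)
  image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
        zlim = c(-1, 1), xlab = "residue index", ylab = "residue index",
        col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

match_region <- function(matrix, region, chain = NULL) {
  labels <- attr(matrix, "labels")
  m <- labels$resseq %in% as.integer(region)
  if (!is.null(chain)) m <- m & labels$chain %in% chain
  which(m)
}

#' Correlated / anticorrelated pair report between two residue regions
#'
#' Lists every residue pair (one in each region) whose correlation is at or
#' above `high_threshold` (the conventional strong-coupling bound is 0.7)
#' or strictly below `low_threshold` (default 0: anticorrelated pairs),
#' with summary statistics -- the tabular counterpart of circling coupled
#' helix blocks on a correlation map.
#'
#' @param matrix A `correlation_matrix` from [dccm()].
#' @param region_a,region_b Integer vectors of residue numbers (inclusive
#'   ranges like `101:120` are natural); both must match matrix labels.
#' @param high_threshold Report pairs with correlation >= this (default 0.7).
#' @param low_threshold Report pairs with correlation < this (default 0).
#' @param chain Optional chain id restriction.
#' @return An object of class `region_pair_report`: `mean`, `min`, `max`,
#'   `high_pairs` and `low_pairs` (data frames `resseq_a`, `resseq_b`,
#'   `correlation`), and the thresholds.
#' @export
region_pair_report <- function(matrix, region_a, region_b,
                               high_threshold = 0.7, low_threshold = 0,
                               chain = NULL) {
  ia <- match_region(matrix, region_a, chain)
  ib <- match_region(matrix, region_b, chain)
  if (!length(ia) || !length(ib)) {
    stop("empty region: no matrix labels match the requested residues")
  }
  labels <- attr(matrix, "labels")
  block <- unclass(matrix)[ia, ib, drop = FALSE]
  pairs <- expand.grid(i = seq_along(ia), j = seq_along(ib))
  vals <- block[cbind(pairs$i, pairs$j)]
  df <- data.frame(resseq_a = labels$resseq[ia][pairs$i],
                   resseq_b = labels$resseq[ib][pairs$j],
                   correlation = vals)
  hi <- df[!is.na(df$correlation) & df$correlation >= high_threshold, ]
  lo <- df[!is.na(df$correlation) & df$correlation < low_threshold, ]
  structure(list(mean = mean(vals, na.rm = TRUE),
                 min = min(vals, na.rm = TRUE),
                 max = max(vals, na.rm = TRUE),
                 high_pairs = hi[order(-hi$correlation), ],
                 low_pairs = lo[order(lo$correlation), ],
                 high_threshold = high_threshold,
                 low_threshold = low_threshold,
                 n_pairs = nrow(df)),
            class = "region_pair_report")
}

#' @export
print.region_pair_report <- function(x, ...) {
  cat(sprintf(paste0("<region_pair_report> %d pairs, mean %.3f ",
                     "[%.3f, %.3f]; %d pair(s) >= %.2f, %d pair(s) < %.2f\n"),
              x$n_pairs, x$mean, x$min, x$max,
              nrow(x$high_pairs), x$high_threshold,
              nrow(x$low_pairs), x$low_threshold))
  invisible(x)
}

#' Paint one correlation-matrix row onto a structure's B-factor column
#'
#' Each residue's B-factor becomes its correlation with the anchor residue
#' (the anchor itself gets 1), so the coupling pattern can be coloured in a
#' molecular viewer. Residues absent from the matrix get 0.
#'
#' @param matrix A `correlation_matrix`.
#' @param structure A `mol_structure`.
#' @param anchor_resseq Residue number of the anchor (must be in the matrix).
#' @param chain Optional chain of the anchor.
#' @return The structure with per-residue correlations in `bfactor`.
#' @export
correlation_to_structure <- function(matrix, structure, anchor_resseq,
                                     chain = NULL) {
  labels <- attr(matrix, "labels")
  ai <- match_region(matrix, anchor_resseq, chain)
  if (length(ai) != 1L) {
    stop("anchor residue must match exactly one matrix label")
  }
  row <- unclass(matrix)[ai, ]
  key_m <- paste(labels$chain, labels$resseq)
  key_s <- paste(structure$atoms$chain, structure$atoms$resseq)
  pos <- match(key_s, key_m)
  miss <- is.na(pos)
  if (any(miss)) {
    message(length(unique(key_s[miss])),
            " residue(s) absent from the matrix; B-factor set to 0")
  }
  b <- ifelse(miss, 0, row[pos])
  b[key_s == key_m[ai]] <- 1
  structure$atoms$bfactor <- b
  structure
}
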
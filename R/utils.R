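# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotation matrix from axis and angle
#'
#' Builds the proper rotation matrix for a right-handed rotation of
#' `angle_deg` degrees about `axis` (Rodrigues formula).
#'
#' @param axis Numeric 3-vector; need not be normalised.
#' @param angle_deg Rotation angle in degrees.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  u <- unit_vec(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Dihedral angle of four points
#'
#' Torsion angle p1-p2-p3-p4 in degrees, in (-180, 180], using the
#' atan2 formulation (stable near 0 and 180 degrees).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Cheap stable rolling digest of a character scalar; used only to label
# run manifests, not for security.
text_digest <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
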
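# Small numeric helpers shared across modules.

#' Root-mean-square of a numeric vector
#' @param x numeric vector.
#' @return scalar RMS.
#' @keywords internal
rms <- function(x) sqrt(mean(x^2))

vnorm <- function(x) sqrt(sum(x^2))

#' Wrap an angle into (-pi, pi]
#' @param x angle in radian.
#' @return equivalent angle in (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- atan2(sin(x), cos(x))
  # atan2 returns values in [-pi, pi]; map -pi to +pi for a half-open interval
  ifelse(y <= -pi, pi, y)
}

#' Circular (arc) distance between two angles
#' @param x,y angles in radian.
#' @return distance in [0, pi].
#' @export
circular_distance <- function(x, y) abs(atan2(sin(x - y), cos(x - y)))

#' Orthonormalize the columns of a matrix
#'
#' Modified Gram-Schmidt with one reorthogonalization pass. Columns that are
#' (numerically) linearly dependent on earlier ones are dropped.
#'
#' @param A numeric matrix.
#' @param tol relative tolerance below which a column is considered dependent.
#' @return matrix with orthonormal columns spanning the column space of `A`.
#' @export
orth_mgs <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  scale <- max(abs(A), 1)
  out <- matrix(0, nrow(A), 0)
  for (j in seq_len(ncol(A))) {
    v <- A[, j]
    for (pass in 1:2) { # reorthogonalize for numerical safety
      if (ncol(out) > 0) v <- v - out %*% crossprod(out, v)
    }
    nv <- vnorm(v)
    if (nv > tol * scale) out <- cbind(out, v / nv)
  }
  unname(out)
}

# Deterministic pseudo-random sign derived from a geometry. Used by model
# backends to emulate the arbitrary wavefunction phase while staying
# deterministic for a fixed q (backend contract).
phase_sign <- function(q, seed = 0) {
  x <- sum(sin(q * (seq_along(q) * 12.9898 + 4.1414) + seed * 0.5453)) * 43758.5453
  if (x - floor(x) < 0.5) 1 else -1
}
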
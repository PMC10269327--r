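# Two-state diabatization: conversion between the adiabatic representation
# (E_A, E_B, s, g, h) and the gauge-fixed pseudodiabatic one (alpha, beta,
# gamma), following the 2x2 Hamiltonian
#
#     H = [[alpha, gamma], [gamma, beta]]
#
# with tau = (alpha+beta)/2, delta = (alpha-beta)/2, lambda = sqrt(delta^2 +
# gamma^2) and the mixing angle omega = atan2(gamma, delta). The adiabats are
# E_A = tau + lambda, E_B = tau - lambda. Gradient relations:
#
#     s = grad tau
#     g = cos(omega) grad delta + sin(omega) grad gamma   (= (grad E_A - grad E_B)/2)
#     h = -sin(omega) grad delta + cos(omega) grad gamma  (difference-scaled
#          nonadiabatic coupling, finite at the seam, defined up to sign)
#
# The diabatization direction fixes omega per geometry against a reference
# gauge (k_delta, k_gamma) taken from a chosen reference structure.

.DEGEN_TOL <- 1e-9 # hartree; below this the gap is treated as exact degeneracy

#' Adiabatic data at one geometry
#'
#' Container for the per-geometry output of an electronic-structure backend:
#' the two state energies, the average gradient `s`, the half
#' gradient-difference `g = (grad E_A - grad E_B)/2`, and the
#' difference-scaled nonadiabatic coupling vector `h` (finite at the seam,
#' defined up to an arbitrary sign). In spin mode (`h_defined = FALSE`) no
#' coupling is available and `h` is stored as zeros.
#'
#' @param q geometry, numeric vector (bohr).
#' @param E_A,E_B state energies (hartree). In `ci` mode (`h_defined = TRUE`)
#'   the states are ordered adiabatically, `E_A >= E_B`. In spin mode the
#'   labels track the (smooth) spin character of the states, so the diabats
#'   may cross and `E_A < E_B` is allowed.
#' @param s average gradient, same length as `q` (hartree/bohr).
#' @param g half gradient-difference (hartree/bohr).
#' @param h coupling vector (hartree/bohr); ignored when `h_defined = FALSE`.
#' @param h_defined logical; `FALSE` for different-spin crossings.
#' @param degenerate logical; `TRUE` when the backend flagged E_A = E_B.
#' @return an object of class `adiabatic_point`.
#' @export
adiabatic_point <- function(q, E_A, E_B, s, g, h = NULL, h_defined = TRUE,
                            degenerate = FALSE) {
  q <- as.numeric(q); m <- length(q)
  if (h_defined && E_A < E_B - .DEGEN_TOL) {
    stop("adiabatic_point: E_A must be >= E_B when the coupling is defined")
  }
  if (is.null(h)) h <- numeric(m)
  stopifnot(length(s) == m, length(g) == m, length(h) == m)
  if (h_defined && !all(is.finite(h))) stop("adiabatic_point: h must be finite when defined")
  if (!all(is.finite(q)) || !all(is.finite(s)) || !all(is.finite(g)) ||
      !is.finite(E_A) || !is.finite(E_B)) {
    stop("adiabatic_point: non-finite input")
  }
  structure(list(q = q, E_A = E_A, E_B = E_B, s = as.numeric(s),
                 g = as.numeric(g), h = as.numeric(h),
                 h_defined = isTRUE(h_defined), degenerate = isTRUE(degenerate)),
            class = "adiabatic_point")
}

#' Diabatic data at one geometry
#'
#' @param q geometry (bohr).
#' @param alpha,beta,gamma diabatic energies (hartree); the diabats may cross,
#'   `alpha >= beta` is not required.
#' @param grad_alpha,grad_beta,grad_gamma gradients (hartree/bohr).
#' @param omega fitted mixing angle (radian).
#' @param h_flipped logical, whether the sign of the input `h` was flipped
#'   during diabatization.
#' @param degenerate logical degeneracy flag carried over from the input.
#' @return an object of class `diabatic_point`.
#' @export
diabatic_point <- function(q, alpha, beta, gamma, grad_alpha, grad_beta,
                           grad_gamma, omega = 0, h_flipped = FALSE,
                           degenerate = FALSE) {
  q <- as.numeric(q); m <- length(q)
  stopifnot(length(grad_alpha) == m, length(grad_beta) == m,
            length(grad_gamma) == m)
  structure(list(q = q, alpha = alpha, beta = beta, gamma = gamma,
                 grad_alpha = as.numeric(grad_alpha),
                 grad_beta = as.numeric(grad_beta),
                 grad_gamma = as.numeric(grad_gamma),
                 omega = omega, h_flipped = isTRUE(h_flipped),
                 degenerate = isTRUE(degenerate)),
            class = "diabatic_point")
}

#' Reference gauge for the pseudodiabatization
#'
#' The gauge is defined by a reference structure `q_ref` together with the
#' constant vectors `k_delta = g(q_ref)` and `k_gamma = h(q_ref)`, which set
#' omega(q_ref) = 0. The vectors are stored with the orientation given;
#' [diabatize_history()] canonicalizes the sign of `k_gamma` before building
#' the gauge so that the diabatic surfaces do not depend on the arbitrary
#' phase of the reference coupling vector.
#'
#' @param q_ref reference geometry (bohr).
#' @param k_delta,k_gamma gauge vectors (hartree/bohr).
#' @param min_angle minimum angle (radian) required between the gauge vectors.
#' @return an object of class `mecp_gauge`.
#' @export
make_gauge <- function(q_ref, k_delta, k_gamma, min_angle = 1e-6) {
  k_delta <- as.numeric(k_delta); k_gamma <- as.numeric(k_gamma)
  nd <- vnorm(k_delta); ng <- vnorm(k_gamma)
  if (nd <= 0 || ng <= 0) stop("make_gauge: gauge vectors must be nonzero")
  cosang <- abs(sum(k_delta * k_gamma)) / (nd * ng)
  if (cosang > cos(min_angle)) {
    stop("make_gauge: k_delta and k_gamma are (nearly) parallel; gauge undefined")
  }
  structure(list(q_ref = as.numeric(q_ref), k_delta = k_delta, k_gamma = k_gamma),
            class = "mecp_gauge")
}

#' Reconstruct adiabatic data from a diabatic point
#'
#' Diagonalizes the 2x2 diabatic Hamiltonian analytically and rotates the
#' diabatic gradients by the local mixing angle `omega = atan2(gamma, delta)`
#' to obtain `g` and `h`. At (numerically) exact degeneracy the angle is
#' undefined and the omega -> 0 limit is returned with the `degenerate` flag
#' set.
#'
#' @param d a [diabatic_point()].
#' @return an [adiabatic_point()].
#' @export
adiabatic_from_diabatic <- function(d) {
  stopifnot(inherits(d, "diabatic_point"))
  tau <- (d$alpha + d$beta) / 2
  delta <- (d$alpha - d$beta) / 2
  lambda <- sqrt(delta^2 + d$gamma^2)
  grad_tau <- (d$grad_alpha + d$grad_beta) / 2
  grad_delta <- (d$grad_alpha - d$grad_beta) / 2
  degen <- lambda < .DEGEN_TOL
  w <- if (degen) 0 else atan2(d$gamma, delta)
  g <- cos(w) * grad_delta + sin(w) * d$grad_gamma
  h <- -sin(w) * grad_delta + cos(w) * d$grad_gamma
  adiabatic_point(q = d$q, E_A = tau + lambda, E_B = tau - lambda,
                  s = grad_tau, g = g, h = h, h_defined = TRUE,
                  degenerate = degen)
}

#' Minimal rotation of the (g, h) plane onto the gauge plane
#'
#' Computes the minimal (SVD-based) rotation taking `span{g, h}` onto
#' `span{k_delta, k_gamma}` and applies it to `g` and `h`. The singular values
#' of the inner-product matrix between the two orthonormalized subspaces are
#' the cosines of the principal angles; their product close to zero signals
#' that the two planes are nearly orthogonal and the transformed vectors are
#' not to be trusted (`conditioning_ok = FALSE`, with a warning).
#'
#' @param g,h branching-plane vectors at the current geometry.
#' @param gauge a [make_gauge()] object.
#' @param cond_threshold flag conditioning when `phi1 * phi2` falls below this.
#' @return list with `g_prime`, `h_prime`, `singular_values` (length 2, in
#'   `[0, 1]`), and `conditioning_ok`.
#' @export
minimal_plane_rotation <- function(g, h, gauge, cond_threshold = 0.1) {
  stopifnot(inherits(gauge, "mecp_gauge"))
  g <- as.numeric(g); h <- as.numeric(h)
  B1 <- orth_mgs(cbind(g, h))
  if (ncol(B1) < 2) stop("minimal_plane_rotation: g and h are (nearly) parallel")
  B2 <- orth_mgs(cbind(gauge$k_delta, gauge$k_gamma))
  if (ncol(B2) < 2) stop("minimal_plane_rotation: degenerate gauge plane")
  sv <- svd(crossprod(B1, B2))
  phi <- pmin(pmax(sv$d, 0), 1)
  ok <- prod(phi) >= cond_threshold
  if (!ok) {
    warning("minimal_plane_rotation: planes nearly orthogonal (phi1*phi2 = ",
            signif(prod(phi), 3), "); omega fit may be inconsistent")
  }
  R <- B2 %*% sv$v %*% t(sv$u) %*% t(B1) # isometry on span{g, h}
  list(g_prime = as.numeric(R %*% g), h_prime = as.numeric(R %*% h),
       singular_values = phi, conditioning_ok = ok)
}

#' Circular mean of two angles
#'
#' Returns the angle equidistant from both arguments along the shorter arc.
#' For antipodal inputs (arc distance pi) the result is the deterministic
#' tie-break `x + pi/2`.
#'
#' @param x,y angles in radian.
#' @return angle in (-pi, pi].
#' @export
circular_mean <- function(x, y) {
  stopifnot(is.finite(x), is.finite(y))
  d <- atan2(sin(y - x), cos(y - x))
  if (abs(abs(d) - pi) < 1e-12) return(wrap_angle(x + pi / 2))
  wrap_angle(x + d / 2)
}

#' Resolve the arbitrary sign of the coupling vector
#'
#' The coupling vector from an electronic-structure calculation carries an
#' arbitrary sign (wavefunction phase). If the two angle estimates differ by
#' more than pi/2 on the circle, `h` is replaced by `-h`, which shifts
#' `omega_h` by pi.
#'
#' @param omega_g,omega_h angle estimates from the g and h vectors (radian).
#' @param h the coupling vector.
#' @return list with `h_out`, `flipped`, and the updated `omega_h`.
#' @export
resolve_h_sign <- function(omega_g, omega_h, h) {
  if (circular_distance(omega_g, omega_h) > pi / 2) {
    list(h_out = -as.numeric(h), flipped = TRUE, omega_h = wrap_angle(omega_h + pi))
  } else {
    list(h_out = as.numeric(h), flipped = FALSE, omega_h = wrap_angle(omega_h))
  }
}

#' Fit the mixing angle against the gauge
#'
#' Expresses the in-plane vectors `g'` and `h'` in the (generally
#' non-orthogonal) basis `(k_delta, k_gamma)` via the Moore-Penrose
#' pseudoinverse and reads off their polar angles. `omega_h` is the raw angle
#' of `h'` shifted by `-pi/2`, so that in the reference gauge both estimates
#' give 0; on data from an exact linear diabatic model both estimates equal
#' the angle of the Moore-Penrose solve for the in-plane rotation. After the
#' coupling-sign resolution the two estimates are combined with
#' [circular_mean()].
#'
#' @param pr result of [minimal_plane_rotation()].
#' @param gauge a [make_gauge()] object.
#' @param override_conditioning evaluate even when `pr$conditioning_ok` is
#'   `FALSE`.
#' @return list with `omega`, `omega_g`, `omega_h` (after sign resolution) and
#'   `h_flipped`.
#' @export
fit_omega <- function(pr, gauge, override_conditioning = TRUE) {
  stopifnot(inherits(gauge, "mecp_gauge"))
  if (!pr$conditioning_ok && !override_conditioning) {
    stop("fit_omega: plane rotation badly conditioned")
  }
  gp <- pr$g_prime; hp <- pr$h_prime
  if (vnorm(gp) == 0 || vnorm(hp) == 0) stop("fit_omega: zero-length g' or h'")
  K <- cbind(gauge$k_delta, gauge$k_gamma)
  cg <- solve(crossprod(K), crossprod(K, gp)) # pseudoinverse coordinates
  ch <- solve(crossprod(K), crossprod(K, hp))
  omega_g <- atan2(cg[2], cg[1])
  omega_h_raw <- wrap_angle(atan2(ch[2], ch[1]) - pi / 2)
  res <- resolve_h_sign(omega_g, omega_h_raw, hp)
  list(omega = circular_mean(omega_g, res$omega_h),
       omega_g = omega_g, omega_h = res$omega_h, h_flipped = res$flipped)
}

#' Diabatize one adiabatic point against a gauge
#'
#' Determines the mixing angle omega of the point from its `(g, h)` pair
#' (rotated into the gauge plane), then splits the adiabatic data into the
#' three diabatic quantities: `delta = lambda cos(omega)`, `gamma = lambda
#' sin(omega)` with `lambda = (E_A - E_B)/2`, and gradients obtained by the
#' inverse in-plane rotation. The round trip through
#' [adiabatic_from_diabatic()] reproduces the input exactly (with `h` up to
#' the recorded sign flip).
#'
#' @param p an [adiabatic_point()].
#' @param gauge a [make_gauge()] object.
#' @return a [diabatic_point()].
#' @export
diabatize_point <- function(p, gauge) {
  stopifnot(inherits(p, "adiabatic_point"), inherits(gauge, "mecp_gauge"))
  lambda <- (p$E_A - p$E_B) / 2
  tau <- (p$E_A + p$E_B) / 2
  at_ref <- isTRUE(all.equal(p$q, gauge$q_ref, tolerance = 1e-12))
  if (vnorm(p$g) == 0 && !at_ref) {
    stop("diabatize_point: degenerate point with undefined branching plane")
  }
  pr <- minimal_plane_rotation(p$g, p$h, gauge)
  fo <- fit_omega(pr, gauge)
  h_use <- if (fo$h_flipped) -p$h else p$h
  w <- fo$omega
  delta <- lambda * cos(w)
  gam <- lambda * sin(w)
  # inverse of the (g, h) = R(omega) (grad delta, grad gamma) rotation
  grad_delta <- cos(w) * p$g - sin(w) * h_use
  grad_gamma <- sin(w) * p$g + cos(w) * h_use
  diabatic_point(q = p$q, alpha = tau + delta, beta = tau - delta, gamma = gam,
                 grad_alpha = p$s + grad_delta, grad_beta = p$s - grad_delta,
                 grad_gamma = grad_gamma, omega = w, h_flipped = fo$h_flipped,
                 degenerate = p$degenerate)
}

#' Diabatize an optimization history
#'
#' In `ci` mode the gauge is built from the last point of the history
#' (`k_delta = g(q_ref)`, `k_gamma = h(q_ref)`, sign-canonicalized) and every
#' point is diabatized against it. In `spin` mode the coupling gamma is
#' identically zero, so `alpha = E_A`, `beta = E_B` directly and no gauge is
#' needed.
#'
#' @param points list of [adiabatic_point()]s; the last one is the reference.
#' @param mode `"ci"` or `"spin"`.
#' @return list with `points` (list of [diabatic_point()]s) and `gauge`
#'   (`NULL` in spin mode).
#' @export
diabatize_history <- function(points, mode = c("ci", "spin")) {
  mode <- match.arg(mode)
  stopifnot(length(points) >= 1)
  if (mode == "spin") {
    out <- lapply(points, function(p) {
      m <- length(p$q)
      diabatic_point(q = p$q, alpha = p$E_A, beta = p$E_B, gamma = 0,
                     grad_alpha = p$s + p$g, grad_beta = p$s - p$g,
                     grad_gamma = numeric(m), omega = 0,
                     degenerate = p$degenerate)
    })
    return(list(points = out, gauge = NULL))
  }
  ref <- points[[length(points)]]
  if (!ref$h_defined) stop("diabatize_history: ci mode requires coupling vectors")
  if (vnorm(ref$g) == 0) {
    stop("diabatize_history: reference point has vanishing g; choose another reference")
  }
  # canonicalize the sign of the reference coupling (largest-magnitude
  # component positive): the diabatic surfaces then do not depend on the
  # arbitrary phase of h at the reference point
  k_gamma <- ref$h
  if (k_gamma[which.max(abs(k_gamma))] < 0) k_gamma <- -k_gamma
  gauge <- make_gauge(ref$q, ref$g, k_gamma)
  list(points = lapply(points, diabatize_point, gauge = gauge), gauge = gauge)
}

#' @export
print.adiabatic_point <- function(x, ...) {
  cat(sprintf("<adiabatic_point> m=%d  E_A=%.8f  E_B=%.8f  gap=%.3e%s\n",
              length(x$q), x$E_A, x$E_B, x$E_A - x$E_B,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
print.diabatic_point <- function(x, ...) {
  cat(sprintf("<diabatic_point> m=%d  alpha=%.8f  beta=%.8f  gamma=%.3e  omega=%.4f%s\n",
              length(x$q), x$alpha, x$beta, x$gamma, x$omega,
              if (x$h_flipped) "  [h flipped]" else ""))
  invisible(x)
}
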
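# Shared oracles and fixture builders. All oracles are independent of the
# implementation paths they check: numeric 2x2 diagonalization, central
# finite differences, brute-force projectors, Moore-Penrose solves.

# central finite-difference gradient of a scalar function
fd_grad <- function(f, q, h = 1e-6) {
  vapply(seq_along(q), function(k) {
    e <- numeric(length(q)); e[k] <- h
    (f(q + e) - f(q - e)) / (2 * h)
  }, numeric(1))
}

# eigenvalues of the 2x2 diabatic Hamiltonian, sorted decreasing
eigen2x2 <- function(alpha, beta, gamma) {
  sort(eigen(matrix(c(alpha, gamma, gamma, beta), 2, 2),
             symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

# a random adiabatic point with a strictly positive gap
random_adiabatic_point <- function(m) {
  gap <- stats::runif(1, 0.05, 1)
  E_B <- -78 + stats::rnorm(1)
  adiabatic_point(q = stats::rnorm(m), E_A = E_B + gap, E_B = E_B,
                  s = stats::rnorm(m), g = stats::rnorm(m), h = stats::rnorm(m))
}

# a random valid gauge in m dimensions (vectors guaranteed non-parallel)
random_gauge <- function(m) {
  repeat {
    kd <- stats::rnorm(m); kg <- stats::rnorm(m)
    ok <- tryCatch({ make_gauge(stats::rnorm(m), kd, kg); TRUE },
                   error = function(e) FALSE)
    if (ok) return(make_gauge(stats::rnorm(m), kd, kg))
  }
}

# exact linear two-state model: alpha, beta, gamma linear in q, plus the
# backend-style adiabatic evaluation, used as the Eq-21 style oracle
linear_diabatic_model <- function(m) {
  k_alpha <- stats::rnorm(m); k_beta <- stats::rnorm(m); k_gamma <- stats::rnorm(m)
  c_alpha <- stats::rnorm(1); c_beta <- stats::rnorm(1); c_gamma <- stats::rnorm(1)
  eval_at <- function(q) {
    d <- diabatic_point(q,
                        alpha = c_alpha + sum(k_alpha * q),
                        beta = c_beta + sum(k_beta * q),
                        gamma = c_gamma + sum(k_gamma * q),
                        grad_alpha = k_alpha, grad_beta = k_beta,
                        grad_gamma = k_gamma)
    adiabatic_from_diabatic(d)
  }
  list(eval_at = eval_at, k_delta = (k_alpha - k_beta) / 2, k_gamma = k_gamma)
}

# rotate a (g, h) pair in-plane by an angle (the 2*chi wavefunction rotation)
rotate_gh <- function(p, ang) {
  g2 <- cos(ang) * p$g + sin(ang) * p$h
  h2 <- -sin(ang) * p$g + cos(ang) * p$h
  adiabatic_point(p$q, p$E_A, p$E_B, p$s, g2, h2, degenerate = p$degenerate)
}

expect_near <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
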
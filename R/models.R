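# Analytic two-state model Hamiltonians with known diabats, seams and MECPs.
# These stand in for an electronic-structure program: the backend diagonalizes
# the model 2x2 Hamiltonian and reports E_A, E_B, s, g, h exactly as a real
# backend would, including (optionally) a pseudo-random sign on the coupling
# vector to emulate the arbitrary wavefunction phase.

# A quadratic scalar field value/gradient: f(q) = c + b.(q-q0) + 1/2 (q-q0)' A (q-q0)
.quad_field <- function(c0, b, A, q0) {
  force(c0); force(b); force(A); force(q0)
  list(value = function(q) {
    dq <- q - q0
    c0 + sum(b * dq) + 0.5 * sum(dq * (A %*% dq))
  },
  gradient = function(q) as.numeric(b + A %*% (q - q0)))
}

.zero_field <- function(m) {
  list(value = function(q) 0, gradient = function(q) numeric(m))
}

#' List the shipped model families
#' @return character vector of family names.
#' @export
model_families <- function() {
  c("linear_cone", "quadratic_cone", "spin_harmonic", "random_poly")
}

# Build the three diabatic fields for a family. Each family returns
# list(alpha, beta, gamma = .quad_field-like, m, known_mecp, description,
# spin = logical).
.model_fields <- function(family, params, seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  switch(family,
    linear_cone = {
      m <- params$m %||% 2L
      k_alpha <- params$k_alpha %||% c(2, 0.5, rep(0.1, max(0, m - 2)))[1:m]
      k_beta <- params$k_beta %||% c(-1, 0.3, rep(-0.1, max(0, m - 2)))[1:m]
      k_gamma <- params$k_gamma %||% c(0, 0.8, rep(0.2, max(0, m - 2)))[1:m]
      c_alpha <- params$c_alpha %||% 0
      c_beta <- params$c_beta %||% 0
      # apex: delta = gamma = 0; solve the 2 x m linear system (minimum norm)
      kd <- (k_alpha - k_beta) / 2
      Jc <- rbind(kd, k_gamma)
      rhs <- -c((c_alpha - c_beta) / 2, 0)
      apex <- as.numeric(t(Jc) %*% solve(tcrossprod(Jc), rhs))
      list(alpha = .quad_field(c_alpha, k_alpha, matrix(0, m, m), numeric(m)),
           beta = .quad_field(c_beta, k_beta, matrix(0, m, m), numeric(m)),
           gamma = .quad_field(0, k_gamma, matrix(0, m, m), numeric(m)),
           m = m, known_mecp = apex, spin = FALSE,
           description = "linear diabats: single conical apex, constant branching plane")
    },
    quadratic_cone = {
      m <- params$m %||% 2L
      # Construct the crossing point q* first, then fields that vanish there:
      # delta and gamma have independent linear parts at q* plus asymmetric
      # quadratic corrections; the average-energy gradient at q* is placed in
      # span{grad delta, grad gamma} so q* is exactly seam-stationary.
      qstar <- params$qstar %||% stats::runif(m, -0.5, 0.5)
      rot <- function(v, ang2) { # generic independent directions
        u <- v / vnorm(v)
        w <- stats::rnorm(m); w <- w - sum(w * u) * u
        if (vnorm(w) < 1e-8) { w <- seq_len(m); w <- w - sum(w * u) * u }
        w / vnorm(w)
      }
      d1 <- params$d1 %||% { v <- stats::rnorm(m); v / vnorm(v) * stats::runif(1, 0.6, 1.2) }
      g1 <- params$g1 %||% {
        u <- rot(d1)
        (0.5 * u + 0.3 * d1 / vnorm(d1)) * stats::runif(1, 0.8, 1.2)
      }
      rsym <- function(scale) {
        A <- matrix(stats::rnorm(m * m, sd = scale), m, m)
        (A + t(A)) / 2
      }
      Dq <- params$Dq %||% rsym(0.15)
      Gq <- params$Gq %||% rsym(0.15)
      Tq <- params$Tq %||% { A <- rsym(0.2); A + diag(m) * 1.0 }
      cf <- params$tau_coef %||% stats::runif(2, -0.4, 0.4)
      tvec <- cf[1] * d1 + cf[2] * g1 # tau gradient at q*: in the branching plane
      tau0 <- params$tau0 %||% -78.0
      tau <- .quad_field(tau0, tvec, Tq, qstar)
      delta <- .quad_field(0, d1, Dq, qstar)
      gam <- .quad_field(0, g1, Gq, qstar)
      list(alpha = list(value = function(q) tau$value(q) + delta$value(q),
                        gradient = function(q) tau$gradient(q) + delta$gradient(q)),
           beta = list(value = function(q) tau$value(q) - delta$value(q),
                       gradient = function(q) tau$gradient(q) - delta$gradient(q)),
           gamma = gam, m = m, known_mecp = qstar, spin = FALSE,
           description = "asymmetric quadratic diabats; exact MECP at the constructed crossing")
    },
    spin_harmonic = {
      mdef <- params$m %||% 2L
      a <- params$a %||% c(-0.7, 0.2, rep(0, max(0, mdef - 2)))[seq_len(mdef)]
      b <- params$b %||% c(0.8, -0.3, rep(0.1, max(0, mdef - 2)))[seq_len(mdef)]
      m <- length(a)
      k <- params$k %||% 0.9
      E_a <- params$E_a %||% -100.0
      E_b <- params$E_b %||% -99.95
      # seam: alpha - beta = 0 is the hyperplane u.q = v; closed-form
      # constrained minimum of the average energy (Lagrange)
      u <- k * (b - a)
      v <- k * (sum(b^2) - sum(a^2)) / 2 - (E_a - E_b)
      cbar <- (a + b) / 2
      mecp <- cbar + u * (v - sum(u * cbar)) / sum(u^2)
      list(alpha = .quad_field(E_a, numeric(m), diag(k, m), a),
           beta = .quad_field(E_b, numeric(m), diag(k, m), b),
           gamma = .zero_field(m), m = m, known_mecp = mecp, spin = TRUE,
           description = "two isotropic paraboloids, gamma = 0; MECP has a closed form")
    },
    random_poly = {
      m <- params$m %||% 2L
      rq <- function(base) {
        A <- matrix(stats::rnorm(m * m, sd = 0.3), m, m); A <- (A + t(A)) / 2
        .quad_field(base + stats::rnorm(1, sd = 0.2), stats::rnorm(m, sd = 0.7),
                    A + diag(m) * 0.5, stats::runif(m, -0.5, 0.5))
      }
      list(alpha = rq(-50), beta = rq(-50), gamma = {
        A <- matrix(stats::rnorm(m * m, sd = 0.2), m, m); A <- (A + t(A)) / 2
        .quad_field(stats::rnorm(1, sd = 0.1), stats::rnorm(m, sd = 0.5), A,
                    stats::runif(m, -0.5, 0.5))
      }, m = m, known_mecp = NULL, spin = FALSE,
      description = "random quadratic diabats (property tests)")
    },
    stop("analytic_backend: unknown model family '", family, "'")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the diabatic fields of a model
#' @param model a `two_state_model`.
#' @param q geometry.
#' @return list with `alpha`, `beta`, `gamma` and their gradients.
#' @export
model_diabats <- function(model, q) {
  f <- model$fields
  list(alpha = f$alpha$value(q), beta = f$beta$value(q),
       gamma = f$gamma$value(q),
       grad_alpha = f$alpha$gradient(q), grad_beta = f$beta$gradient(q),
       grad_gamma = f$gamma$gradient(q))
}

#' Analytic two-state model backend
#'
#' Builds one of the shipped model Hamiltonians and wraps it as a backend
#' callable: a function of the geometry returning an [adiabatic_point()]
#' obtained by diagonalizing the model's 2x2 diabatic Hamiltonian. With
#' `random_phase = TRUE` the sign of the coupling vector is flipped
#' pseudo-randomly (but deterministically for a fixed geometry), emulating
#' the arbitrary wavefunction phase of a real electronic-structure program.
#'
#' @param family one of [model_families()].
#' @param params named list of family-specific parameters (all optional).
#' @param seed integer seed controlling randomized parameters; the same seed
#'   always yields the same model.
#' @param random_phase randomize the sign of `h` per geometry.
#' @return list with `model` (class `two_state_model`) and `backend` (the
#'   callable).
#' @export
analytic_backend <- function(family = model_families(), params = list(),
                             seed = NULL, random_phase = FALSE) {
  family <- match.arg(family)
  fields <- .model_fields(family, params, seed)
  model <- structure(list(family = family, fields = fields, m = fields$m,
                          known_mecp = fields$known_mecp, spin = fields$spin,
                          description = fields$description),
                     class = "two_state_model")
  phase_seed <- if (is.null(seed)) 0 else seed
  backend <- function(q) {
    q <- as.numeric(q)
    stopifnot(length(q) == model$m)
    d <- model_diabats(model, q)
    dp <- diabatic_point(q = q, alpha = d$alpha, beta = d$beta,
                         gamma = d$gamma, grad_alpha = d$grad_alpha,
                         grad_beta = d$grad_beta, grad_gamma = d$grad_gamma)
    p <- adiabatic_from_diabatic(dp)
    if (model$spin) {
      # spin labels are smooth: report the states in diabatic (spin) order,
      # not energy order, so the fitted surfaces stay differentiable
      return(adiabatic_point(q = q, E_A = d$alpha, E_B = d$beta,
                             s = (d$grad_alpha + d$grad_beta) / 2,
                             g = (d$grad_alpha - d$grad_beta) / 2,
                             h_defined = FALSE,
                             degenerate = abs(d$alpha - d$beta) < 2e-9))
    }
    if (random_phase && phase_sign(q, phase_seed) < 0) {
      p$h <- -p$h
    }
    p
  }
  list(model = model, backend = backend)
}

#' Brute-force MECP oracle
#'
#' Independent of the optimizer: scans a grid for small-gap regions, then
#' minimizes the penalty function `tau + c (delta^2 + gamma^2)` (a smooth
#' quantity even at the seam, since `(E_A - E_B)^2 = 4 (delta^2 + gamma^2)`)
#' with increasing penalty weight and warm starts.
#'
#' @param model a `two_state_model`.
#' @param bounds matrix `m x 2` of lower/upper bounds containing the seam, or
#'   a single numeric half-width around the origin.
#' @param resolution grid points per dimension for the initial scan.
#' @param penalty_weights increasing penalty schedule.
#' @param gap_tol maximum acceptable gap at the solution (hartree).
#' @return the constrained minimizer `q_star`.
#' @export
brute_force_mecp <- function(model, bounds = 1.5, resolution = 31,
                             penalty_weights = 10^seq(2, 8),
                             gap_tol = 1e-4) {
  m <- model$m
  if (is.null(dim(bounds))) bounds <- cbind(rep(-bounds, m), rep(bounds, m))
  axes <- lapply(seq_len(m), function(k) {
    seq(bounds[k, 1], bounds[k, 2], length.out = resolution)
  })
  grid <- as.matrix(expand.grid(axes))
  pen0 <- apply(grid, 1, function(q) {
    d <- model_diabats(model, q)
    delta <- (d$alpha - d$beta) / 2
    (d$alpha + d$beta) / 2 + penalty_weights[1] * (delta^2 + d$gamma^2)
  })
  q <- grid[which.min(pen0), ]
  for (cw in penalty_weights) {
    fn <- function(qq) {
      d <- model_diabats(model, qq)
      delta <- (d$alpha - d$beta) / 2
      (d$alpha + d$beta) / 2 + cw * (delta^2 + d$gamma^2)
    }
    gr <- function(qq) {
      d <- model_diabats(model, qq)
      delta <- (d$alpha - d$beta) / 2
      gd <- (d$grad_alpha - d$grad_beta) / 2
      (d$grad_alpha + d$grad_beta) / 2 +
        cw * (2 * delta * gd + 2 * d$gamma * d$grad_gamma)
    }
    q <- stats::optim(q, fn, gr, method = "L-BFGS-B",
                      lower = bounds[, 1], upper = bounds[, 2],
                      control = list(maxit = 500, factr = 10))$par
  }
  d <- model_diabats(model, q)
  gap <- 2 * sqrt(((d$alpha - d$beta) / 2)^2 + d$gamma^2)
  if (gap > gap_tol) {
    stop("brute_force_mecp: no seam point found within bounds (residual gap ",
         signif(gap, 3), ")")
  }
  as.numeric(q)
}

#' Generate a fixture history around a geometry
#'
#' Deterministic pseudo-random geometries within `spread` of `around`,
#' evaluated through the backend. Used to exercise [diabatize_history()] and
#' [build_surrogate()] without running the optimizer.
#'
#' @param backend backend callable (from [analytic_backend()]).
#' @param around center geometry.
#' @param n_points number of points (>= 1).
#' @param spread uniform half-width of the perturbations (bohr).
#' @param seed RNG seed.
#' @return list of [adiabatic_point()]s.
#' @export
generate_history <- function(backend, around, n_points, spread = 0.3,
                             seed = 1) {
  stopifnot(n_points >= 1)
  around <- as.numeric(around)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- vector("list", n_points)
  for (i in seq_len(n_points)) {
    repeat {
      qi <- around + stats::runif(length(around), -spread, spread)
      dup <- FALSE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          if (vnorm(qi - out[[j]]$q) <= 1e-6) { dup <- TRUE; break }
        }
      }
      if (!dup) break
    }
    out[[i]] <- backend(qi)
  }
  out
}

#' Load a model backend from a YAML definition
#'
#' The file must contain `family:` plus optional `params:`, `seed:` and
#' `random_phase:` entries.
#'
#' @param path YAML file path.
#' @return as [analytic_backend()].
#' @export
backend_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$family)) stop("backend_from_yaml: missing 'family'")
  analytic_backend(spec$family, params = spec$params %||% list(),
                   seed = spec$seed, random_phase = isTRUE(spec$random_phase))
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf("<two_state_model> %s (m=%d)%s\n  %s\n", x$family, x$m,
              if (x$spin) " [spin]" else "", x$description))
  invisible(x)
}
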
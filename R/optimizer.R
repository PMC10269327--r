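# Restricted-variance optimization of minimum-energy crossing points.
#
# Macroiterations call the electronic-structure backend once and rebuild the
# pseudodiabatic surrogate; microiterations walk the surrogate with a
# projected constrained step: the constrained subspace restores the
# degeneracy (Gauss-Newton on the diabatic residuals), the complementary
# subspace minimizes the average energy with a restricted-step
# rational-function (RS-RFO-style) step. Steps are limited by the surrogate's
# predicted variance: a microiteration that would leave the trusted region is
# pulled back onto the variance limit by bisection and triggers a new backend
# evaluation.

#' Optimizer configuration
#'
#' Convergence thresholds follow common practice for geometry optimization:
#' rms step below 1.2e-3 bohr, rms projected gradient below 3.0e-4
#' hartree/bohr, maximum components at most 1.5 times those values, and the
#' state energy difference below 1e-5 hartree.
#'
#' The default `variance_limit` corresponds to a 95% confidence half-width
#' (1.96 sigma) of 0.3 on the energy surfaces: `(0.3/1.96)^2`.
#'
#' @param mode `"ci"` or `"spin"`.
#' @param conv_rms_step rms step threshold (bohr).
#' @param conv_rms_grad rms projected-gradient threshold (hartree/bohr).
#' @param conv_max_factor max-component factor relative to the rms thresholds.
#' @param conv_ediff energy-difference threshold (hartree).
#' @param max_macro,max_micro iteration caps.
#' @param micro_conv_factor microiterations declare surrogate stationarity at
#'   this fraction of the macro convergence thresholds (the surrogate is
#'   analytic and cheap, so it is converged essentially exactly before the
#'   next backend call).
#' @param variance_limit maximum allowed predicted variance at accepted
#'   microiteration endpoints.
#' @param trust_radius_init trust radius for a single micro step (bohr).
#' @param hessian_diag diagonal approximate Hessian used to calibrate the
#'   characteristic lengths (hartree/bohr^2); recycled to the dimensionality
#'   if scalar. Default 1.
#' @param mu_offset baseline elevation for the GEK energy surfaces (hartree).
#' @param nugget GEK nugget.
#' @param max_data surrogate data window (most recent points).
#' @param project_rigid project overall translations/rotations out of
#'   gradients and steps (requires the coordinates to be atomic Cartesians,
#'   i.e. a dimensionality divisible by 3 with at least 2 atoms).
#' @return an object of class `opt_config`.
#' @export
opt_config <- function(mode = c("ci", "spin"),
                       conv_rms_step = 1.2e-3,
                       conv_rms_grad = 3.0e-4,
                       conv_max_factor = 1.5,
                       conv_ediff = 1e-5,
                       max_macro = 50,
                       max_micro = 40,
                       micro_conv_factor = 1e-4,
                       variance_limit = (0.3 / 1.96)^2,
                       trust_radius_init = 0.3,
                       hessian_diag = 1,
                       mu_offset = 10,
                       nugget = 1e-10,
                       max_data = 20,
                       project_rigid = FALSE) {
  mode <- match.arg(mode)
  thr <- c(conv_rms_step, conv_rms_grad, conv_max_factor, conv_ediff,
           max_macro, max_micro, variance_limit, trust_radius_init, mu_offset)
  stopifnot(all(thr > 0))
  structure(list(mode = mode, conv_rms_step = conv_rms_step,
                 conv_rms_grad = conv_rms_grad,
                 conv_max_factor = conv_max_factor, conv_ediff = conv_ediff,
                 max_macro = max_macro, max_micro = max_micro,
                 micro_conv_factor = micro_conv_factor,
                 variance_limit = variance_limit,
                 trust_radius_init = trust_radius_init,
                 hessian_diag = hessian_diag, mu_offset = mu_offset,
                 nugget = nugget, max_data = max_data,
                 project_rigid = project_rigid),
            class = "opt_config")
}

# Orthonormal basis of overall translations and rotations at geometry q
# (atomic Cartesian coordinates, m = 3N). Used to project rigid-body modes
# out of gradients and steps.
rigid_mode_basis <- function(q) {
  m <- length(q)
  if (m %% 3 != 0 || m < 6) stop("rigid_mode_basis: need 3N coordinates, N >= 2")
  n_at <- m / 3
  xyz <- matrix(q, ncol = 3, byrow = TRUE)
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  B <- matrix(0, m, 6)
  for (k in 1:3) B[seq(k, m, by = 3), k] <- 1 # translations
  ax <- diag(3)
  for (k in 1:3) { # rotations about the three axes through the centroid
    rot <- t(apply(xyz, 1, function(r) pracma_cross(ax[k, ], r)))
    B[, 3 + k] <- as.numeric(t(rot))
  }
  orth_mgs(B)
}

# cross product without extra dependencies
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Restricted-step rational-function step in a reduced space: the RFO step if
# it fits in the trust radius, otherwise a Levenberg-style step of exactly
# that length (found by bisection on the shift).
trust_region_step <- function(H, grad, radius) {
  k <- length(grad)
  if (k == 0 || vnorm(grad) == 0 && all(abs(H) < 1e-300)) return(numeric(k))
  A <- rbind(cbind(H, grad), c(grad, 0))
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, k + 1]
  if (abs(v[k + 1]) > 1e-12) {
    step <- v[seq_len(k)] / v[k + 1]
    if (vnorm(step) <= radius) return(step)
  }
  evH <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  lo <- max(0, -min(evH)) + 1e-12
  hi <- lo + 1
  while (vnorm(solve(H + diag(hi, k), -grad)) > radius) hi <- hi * 2
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    st <- tryCatch(solve(H + diag(mid, k), -grad), error = function(e) NULL)
    if (is.null(st) || vnorm(st) > radius) lo <- mid else hi <- mid
  }
  solve(H + diag(hi, k), -grad)
}

# Core projected constrained step. residual (length c) and jacobian (c x m)
# define the constrained subspace; the Gauss-Newton restoration drives the
# residuals to zero, and an RS-RFO-style step minimizes the average energy in
# the orthogonal complement.
pco_step <- function(s, hessian, residual, jacobian, trust,
                     rigid_basis = NULL) {
  J <- rbind(jacobian)
  m <- ncol(J)
  if (!is.null(rigid_basis)) {
    P_rig <- diag(m) - tcrossprod(rigid_basis)
    J <- J %*% P_rig
    s <- as.numeric(P_rig %*% s)
    hessian <- P_rig %*% hessian %*% P_rig
  }
  if (any(sqrt(rowSums(J^2)) < 1e-14)) {
    stop("pco_step: vanishing constraint gradient (degenerate branching plane)")
  }
  JJt <- tcrossprod(J)
  step_c <- -as.numeric(t(J) %*% solve(JJt, residual))
  # orthonormal basis of the optimized (tangent) subspace
  Jn <- t(qr.Q(qr(t(J))))
  full <- if (is.null(rigid_basis)) diag(m) else
    orth_mgs(diag(m) - tcrossprod(rigid_basis))
  Z <- orth_mgs(full - t(Jn) %*% (Jn %*% full))
  step_t <- numeric(m)
  if (ncol(Z) > 0) {
    gz <- as.numeric(crossprod(Z, s))
    Hz <- crossprod(Z, hessian %*% Z)
    Hz <- (Hz + t(Hz)) / 2
    rem <- sqrt(max(trust^2 - min(vnorm(step_c), trust)^2, 0))
    if (rem > 0) step_t <- as.numeric(Z %*% trust_region_step(Hz, gz, rem))
  }
  step <- step_c + step_t
  ns <- vnorm(step)
  if (ns > trust) step <- step * (trust / ns)
  step
}

#' Projected constrained step toward the crossing seam
#'
#' Splits the coordinates into a one-dimensional constrained subspace along
#' the gradient-difference vector `g` and its orthogonal complement. The
#' constrained component is a Newton step driving `E_A - E_B` to zero (length
#' `lambda/||g||` to first order, `lambda = (E_A - E_B)/2`); the complement
#' minimizes the average energy via a restricted-step rational-function step
#' using `approx_hessian`. The total step length is capped at `trust`.
#'
#' This is the step used in spin mode, where the gap is differentiable. In
#' `ci` mode the optimizer augments the constrained subspace with the
#' coupling direction (both diabatic residuals `delta` and `gamma` are driven
#' to zero), which is handled internally by [microiterate()].
#'
#' @param E_A,E_B state energies (hartree).
#' @param s average gradient (hartree/bohr).
#' @param g half gradient-difference (hartree/bohr); must be nonzero.
#' @param approx_hessian approximate Hessian of the average energy (m x m).
#' @param trust trust radius (bohr).
#' @return step vector (bohr).
#' @export
projected_constrained_step <- function(E_A, E_B, s, g, approx_hessian, trust) {
  g <- as.numeric(g)
  if (vnorm(g) < 1e-14) {
    stop("projected_constrained_step: zero g (degenerate branching plane)")
  }
  pco_step(as.numeric(s), approx_hessian, (E_A - E_B) / 2, rbind(g), trust)
}

# Approximate Hessian of the surrogate average energy by central finite
# differences of the predicted gradients (the surrogate is analytic, so this
# is cheap and accurate).
surrogate_tau_hessian <- function(surrogate, q, step = 1e-4) {
  m <- length(q)
  H <- matrix(0, m, m)
  for (k in seq_len(m)) {
    e <- numeric(m); e[k] <- step
    gp <- evaluate_adiabatic(surrogate, q + e)$diabatic$grad_tau
    gm <- evaluate_adiabatic(surrogate, q - e)$diabatic$grad_tau
    H[, k] <- (gp - gm) / (2 * step)
  }
  (H + t(H)) / 2
}

# Constraint residuals and Jacobian on the surrogate at q.
surrogate_constraints <- function(ev, mode) {
  d <- ev$diabatic
  if (mode == "ci") {
    list(residual = c(d$delta, d$gamma),
         jacobian = rbind(d$grad_delta, d$grad_gamma))
  } else {
    list(residual = d$delta, jacobian = rbind(d$grad_delta))
  }
}

#' Microiterations on the surrogate
#'
#' Repeats projected constrained steps on surrogate predictions starting from
#' `q_start`, until (i) the surrogate point is stationary (gap, projected
#' gradient and step below `micro_conv_factor` times the convergence
#' thresholds), (ii) a step
#' would exceed the variance limit, in which case the geometry is pulled back
#' onto the limit surface by bisection, or (iii) `max_micro` is reached.
#'
#' @param surrogate a `pd_surrogate`.
#' @param q_start starting geometry (bohr).
#' @param config an [opt_config()].
#' @return list with `q` (candidate geometry), `stop_reason` one of
#'   `"stationary"`, `"variance"`, `"max_iter"`, and `variance` (predicted
#'   variance at the candidate).
#' @export
microiterate <- function(surrogate, q_start, config) {
  stopifnot(inherits(surrogate, "pd_surrogate"), inherits(config, "opt_config"))
  q <- as.numeric(q_start)
  m <- length(q)
  rigid <- if (isTRUE(config$project_rigid)) rigid_mode_basis(q) else NULL
  reason <- "max_iter"
  for (it in seq_len(config$max_micro)) {
    ev <- evaluate_adiabatic(surrogate, q)
    con <- surrogate_constraints(ev, surrogate$mode)
    H <- surrogate_tau_hessian(surrogate, q)
    s <- ev$diabatic$grad_tau
    step <- pco_step(s, H, con$residual, con$jacobian, config$trust_radius_init,
                     rigid_basis = rigid)
    gap <- 2 * sqrt(sum(con$residual^2))
    J <- con$jacobian
    Pg <- s - t(J) %*% solve(tcrossprod(J), J %*% s)
    if (!is.null(rigid)) Pg <- Pg - rigid %*% crossprod(rigid, Pg)
    f_mic <- config$micro_conv_factor
    if (gap <= f_mic * config$conv_ediff &&
        rms(Pg) <= f_mic * config$conv_rms_grad &&
        rms(step) <= f_mic * config$conv_rms_step) {
      reason <- "stationary"
      break
    }
    q_new <- q + step
    if (surrogate_variance(surrogate, q_new) > config$variance_limit) {
      # pull back onto the variance limit surface along the step direction
      lo <- 0; hi <- 1
      for (b in 1:60) {
        mid <- (lo + hi) / 2
        if (surrogate_variance(surrogate, q + mid * step) > config$variance_limit) {
          hi <- mid
        } else {
          lo <- mid
        }
      }
      q <- q + lo * step
      reason <- "variance"
      break
    }
    q <- q_new
  }
  list(q = q, stop_reason = reason, variance = surrogate_variance(surrogate, q))
}

#' Convergence test for the macroiteration loop
#'
#' Converged when, at the latest backend point: rms step and rms projected
#' gradient are at or below their thresholds, the corresponding maximum
#' components are at or below `conv_max_factor` times those thresholds, and
#' the energy gap `|E_A - E_B|` is at or below `conv_ediff`. The projected
#' gradient removes the branching-plane directions (`g` and `h` in `ci`
#' mode, `g` in spin mode) from the average gradient `s`.
#'
#' @param state list with at least `history` (list of [adiabatic_point()]s,
#'   length >= 2).
#' @param config an [opt_config()].
#' @return logical flag.
#' @export
check_convergence <- function(state, config) {
  h <- state$history
  n <- length(h)
  stopifnot(n >= 2)
  p <- h[[n]]
  step <- p$q - h[[n - 1]]$q
  gap <- abs(p$E_A - p$E_B)
  B <- if (config$mode == "ci") orth_mgs(cbind(p$g, p$h)) else
    orth_mgs(cbind(p$g))
  pg <- p$s - B %*% crossprod(B, p$s)
  if (isTRUE(config$project_rigid)) {
    rb <- rigid_mode_basis(p$q)
    pg <- pg - rb %*% crossprod(rb, pg)
  }
  rms(step) <= config$conv_rms_step &&
    max(abs(step)) <= config$conv_max_factor * config$conv_rms_step &&
    rms(pg) <= config$conv_rms_grad &&
    max(abs(pg)) <= config$conv_max_factor * config$conv_rms_grad &&
    gap <= config$conv_ediff
}

#' Optimize a minimum-energy crossing point
#'
#' Macroiteration loop: evaluate the backend, append to the history, rebuild
#' the pseudodiabatic surrogate, microiterate on it, and test convergence.
#' Non-convergence within `max_macro` returns `converged = FALSE` with the
#' full trace rather than an error.
#'
#' @param backend function taking a geometry vector and returning an
#'   [adiabatic_point()] (deterministic for fixed input).
#' @param q0 starting geometry (bohr).
#' @param config an [opt_config()].
#' @return an object of class `mecp_opt`: list with `history`, `q` (final
#'   geometry), `converged`, `macroiterations`, and `trace` (one data-frame
#'   row per macroiteration).
#' @export
optimize_mecp <- function(backend, q0, config = opt_config()) {
  stopifnot(is.function(backend), inherits(config, "opt_config"))
  q0 <- as.numeric(q0)
  m <- length(q0)
  hd <- rep_len(config$hessian_diag, m)
  lengths <- lengths_from_hessian(hd, config$mu_offset)
  eval_backend <- function(q) {
    p <- tryCatch(backend(q), error = function(e) {
      stop(sprintf("optimize_mecp: backend failed at geometry [%s]: %s",
                   paste(signif(q, 8), collapse = ", "),
                   conditionMessage(e)), call. = FALSE)
    })
    if (!inherits(p, "adiabatic_point")) {
      stop("optimize_mecp: backend must return an adiabatic_point")
    }
    p
  }
  history <- list(eval_backend(q0))
  trace <- list()
  converged <- FALSE
  macro <- 0L
  while (macro < config$max_macro) {
    macro <- macro + 1L
    sur <- build_surrogate(history, mode = config$mode, lengths = lengths,
                           nugget = config$nugget,
                           mu_offset = config$mu_offset,
                           max_data = config$max_data)
    q_cur <- history[[length(history)]]$q
    mic <- microiterate(sur, q_cur, config)
    p_new <- eval_backend(mic$q)
    history[[length(history) + 1L]] <- p_new
    step <- mic$q - q_cur
    trace[[macro]] <- data.frame(
      macro = macro, E_A = p_new$E_A, E_B = p_new$E_B,
      gap = abs(p_new$E_A - p_new$E_B), rms_step = rms(step),
      max_step = max(abs(step)), variance = mic$variance,
      stop_reason = mic$stop_reason, stringsAsFactors = FALSE)
    if (check_convergence(list(history = history), config)) {
      converged <- TRUE
      break
    }
  }
  structure(list(history = history, q = history[[length(history)]]$q,
                 converged = converged, macroiterations = macro,
                 trace = do.call(rbind, trace)),
            class = "mecp_opt")
}

#' @export
print.mecp_opt <- function(x, ...) {
  n <- length(x$history)
  p <- x$history[[n]]
  cat(sprintf("<mecp_opt> %s after %d macroiterations\n  E_A=%.8f  E_B=%.8f  gap=%.3e\n",
              if (x$converged) "converged" else "NOT converged",
              x$macroiterations, p$E_A, p$E_B, abs(p$E_A - p$E_B)))
  invisible(x)
}
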
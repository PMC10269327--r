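test_that("a converged point produces a zero step", {
  H <- diag(2)
  step <- projected_constrained_step(E_A = -78, E_B = -78, s = c(0, 0),
                                     g = c(1, 0), approx_hessian = H,
                                     trust = 0.3)
  expect_equal(step, c(0, 0))
  # s parallel to g: the projected (tangent) gradient vanishes too
  step2 <- projected_constrained_step(-78, -78, s = c(0.4, 0), g = c(1, 0),
                                      approx_hessian = H, trust = 0.3)
  expect_lt(max(abs(step2)), 1e-12)
})

test_that("constraint restoration is a Newton step of length lambda over |g|", {
  g <- c(0.8, -0.6)
  lambda <- 0.01
  step <- projected_constrained_step(E_A = -78 + lambda, E_B = -78 - lambda,
                                     s = c(0, 0), g = g,
                                     approx_hessian = diag(2), trust = 0.5)
  expect_equal(as.numeric(step), -lambda * g / sum(g^2), tolerance = 1e-12)
  expect_equal(sqrt(sum(step^2)), lambda / sqrt(sum(g^2)), tolerance = 1e-12)
  # capped by the trust radius
  big <- projected_constrained_step(-70, -86, s = c(0, 0), g = g,
                                    approx_hessian = diag(2), trust = 0.05)
  expect_equal(sqrt(sum(big^2)), 0.05, tolerance = 1e-12)
  expect_error(projected_constrained_step(-78, -79, c(0, 1), c(0, 0), diag(2), 0.3),
               "zero g")
})

test_that("iterated steps reach the constrained minimizer of a quadratic model with a linear seam", {
  # spin-type 2-D model: quadratic average energy, linear gap
  A <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  b <- c(-0.5, 0.7)
  u <- c(1, -1) # gap gradient: E_A - E_B = 2 u.q
  tau <- function(q) sum(b * q) + 0.5 * sum(q * (A %*% q))
  q <- c(0.8, 0.4)
  for (it in 1:60) {
    lam <- sum(u * q)
    step <- projected_constrained_step(tau(q) + lam, tau(q) - lam,
                                       s = b + A %*% q, g = u,
                                       approx_hessian = A, trust = 0.5)
    q <- q + step
  }
  # penalty-method oracle
  q_or <- c(0.8, 0.4)
  for (cw in 10^seq(2, 9)) {
    q_or <- stats::optim(q_or, function(qq) tau(qq) + cw * sum(u * qq)^2,
                         function(qq) b + A %*% qq + 2 * cw * sum(u * qq) * u,
                         method = "BFGS", control = list(reltol = 1e-16))$par
  }
  expect_lt(max(abs(q - q_or)), 1e-8)
  expect_lt(abs(sum(u * q)), 1e-12)
})

test_that("microiterations respect the variance limit and detect stationarity", {
  be <- analytic_backend("quadratic_cone", seed = 2)
  cfg <- opt_config(mode = "ci")
  lengths <- lengths_from_hessian(rep_len(cfg$hessian_diag, 2), cfg$mu_offset)
  # single-point history: candidate must stay inside the trusted region
  p0 <- be$backend(be$model$known_mecp + c(0.3, -0.2))
  sur1 <- build_surrogate(list(p0), mode = "ci", lengths = lengths)
  mic1 <- microiterate(sur1, p0$q, cfg)
  expect_lte(mic1$variance, cfg$variance_limit + 1e-9)
  if (mic1$stop_reason == "variance") {
    expect_gt(mic1$variance, cfg$variance_limit * 0.5) # actually on the limit
  }
  # a richer history around the MECP: the surrogate stationary point is found
  hist <- generate_history(be$backend, be$model$known_mecp, 10, spread = 0.25,
                           seed = 3)
  sur2 <- build_surrogate(hist, mode = "ci", lengths = lengths)
  mic2 <- microiterate(sur2, be$model$known_mecp + c(0.02, 0.01), cfg)
  expect_lte(mic2$variance, cfg$variance_limit + 1e-9)
  ev <- evaluate_adiabatic(sur2, mic2$q)
  if (mic2$stop_reason == "stationary") {
    expect_lt(abs(ev$point$E_A - ev$point$E_B), cfg$conv_ediff)
  }
  # starting at a stationary point returns it unchanged
  mic3 <- microiterate(sur2, mic2$q, cfg)
  if (mic2$stop_reason == "stationary") {
    expect_equal(mic3$q, mic2$q)
    expect_equal(mic3$stop_reason, "stationary")
  }
})

test_that("convergence test honours all thresholds with boundary equality", {
  cfg <- opt_config(mode = "ci")
  m <- 4
  mk <- function(q, gap, s) {
    # energies centred at zero so the boundary gap is exactly representable
    adiabatic_point(q, E_A = gap / 2, E_B = -gap / 2, s = s,
                    g = c(1, 0, 0, 0), h = c(0, 1, 0, 0))
  }
  base <- mk(numeric(m), 0, numeric(m))
  # all metrics zero
  expect_true(check_convergence(list(history = list(base, base)), cfg))
  # gap alone violates
  st <- list(history = list(base, mk(numeric(m), 2e-5, numeric(m))))
  expect_false(check_convergence(st, cfg))
  # gap exactly at the limit passes (<= convention)
  st <- list(history = list(base, mk(numeric(m), 1e-5, numeric(m))))
  expect_true(check_convergence(st, cfg))
  # projected gradient: components along g and h are ignored
  st <- list(history = list(base, mk(numeric(m), 0, c(5, 5, 0, 0))))
  expect_true(check_convergence(st, cfg))
  st <- list(history = list(base, mk(numeric(m), 0, c(0, 0, 1e-3, 0))))
  expect_false(check_convergence(st, cfg))
  # step exactly at the rms limit passes; a larger one fails
  q_at <- rep(cfg$conv_rms_step, m)
  expect_true(check_convergence(list(history = list(base, mk(q_at, 0, numeric(m)))), cfg))
  q_over <- rep(1.01 * cfg$conv_rms_step, m)
  expect_false(check_convergence(list(history = list(base, mk(q_over, 0, numeric(m)))), cfg))
  # max-component rule: rms fine but one component beyond 1.5x
  q_max <- c(1.9 * cfg$conv_rms_step, 0, 0, 0)
  expect_false(check_convergence(list(history = list(base, mk(q_max, 0, numeric(m)))), cfg))
})

test_that("starting at the exact MECP converges immediately", {
  be <- analytic_backend("quadratic_cone", seed = 4)
  res <- optimize_mecp(be$backend, be$model$known_mecp, opt_config(mode = "ci"))
  expect_true(res$converged)
  expect_lte(res$macroiterations, 2)
  expect_lt(max(abs(res$q - be$model$known_mecp)), 1e-6)
})

test_that("CI-mode optimization recovers the brute-force MECP", {
  for (seed in c(3, 8)) {
    be <- analytic_backend("quadratic_cone", seed = seed)
    res <- optimize_mecp(be$backend, be$model$known_mecp + c(0.4, -0.3),
                         opt_config(mode = "ci"))
    expect_true(res$converged)
    q_or <- brute_force_mecp(be$model, bounds = 1.5)
    expect_lt(max(abs(res$q - q_or)), 1e-4)
    p <- res$history[[length(res$history)]]
    expect_lte(abs(p$E_A - p$E_B), 1e-5)
    expect_lte(res$macroiterations, 25)
    # every accepted candidate respected the variance limit
    expect_true(all(res$trace$variance <= opt_config()$variance_limit + 1e-9))
  }
})

test_that("random coupling phases do not harm CI-mode convergence", {
  be <- analytic_backend("quadratic_cone", seed = 6, random_phase = TRUE)
  res <- optimize_mecp(be$backend, be$model$known_mecp + c(-0.3, 0.35),
                       opt_config(mode = "ci"))
  expect_true(res$converged)
  expect_lt(max(abs(res$q - be$model$known_mecp)), 1e-4)
})

test_that("spin-mode optimization reaches the closed-form constrained minimum", {
  be <- analytic_backend("spin_harmonic")
  res <- optimize_mecp(be$backend, c(0.5, 0.9), opt_config(mode = "spin"))
  expect_true(res$converged)
  expect_lt(max(abs(res$q - be$model$known_mecp)), 1e-6)
  p <- res$history[[length(res$history)]]
  expect_lte(abs(p$E_A - p$E_B), 1e-5)
})

test_that("convergence metrics shrink over the final macroiterations", {
  be <- analytic_backend("quadratic_cone", seed = 12)
  res <- optimize_mecp(be$backend, be$model$known_mecp + c(0.35, 0.25),
                       opt_config(mode = "ci"))
  expect_true(res$converged)
  n <- nrow(res$trace)
  if (n >= 3) {
    crit <- pmax(res$trace$gap, res$trace$rms_step)
    expect_true(all(diff(crit[(n - 2):n]) < 0))
  }
})

test_that("non-convergence yields a flag and full trace rather than an error", {
  be <- analytic_backend("quadratic_cone", seed = 2)
  cfg <- opt_config(mode = "ci", max_macro = 2)
  res <- optimize_mecp(be$backend, be$model$known_mecp + c(0.5, 0.5), cfg)
  expect_s3_class(res, "mecp_opt")
  expect_false(res$converged)
  expect_equal(nrow(res$trace), 2)
})

test_that("backend failures propagate with the offending geometry", {
  bad <- function(q) stop("scf blew up")
  expect_error(optimize_mecp(bad, c(0.1, 0.2), opt_config()),
               "backend failed at geometry .*0.1.*scf blew up")
})

test_that("optimization is equivariant under rigid motion of an atomic model", {
  # two-atom spin crossing depending only on the interatomic distance:
  # alpha and beta are harmonic in r with different equilibria
  mk_backend <- function(shift) {
    function(q) {
      x <- matrix(q, ncol = 3, byrow = TRUE) - matrix(shift, 2, 3, byrow = TRUE)
      dvec <- x[1, ] - x[2, ]
      r <- sqrt(sum(dvec^2))
      dr <- c(dvec, -dvec) / r # d r / d q
      alpha <- -100 + 0.6 * (r - 2.0)^2
      beta <- -99.98 + 0.8 * (r - 2.6)^2
      adiabatic_point(q, E_A = alpha, E_B = beta,
                      s = (1.2 * (r - 2.0) + 1.6 * (r - 2.6)) / 2 * dr,
                      g = (1.2 * (r - 2.0) - 1.6 * (r - 2.6)) / 2 * dr,
                      h_defined = FALSE)
    }
  }
  # crossing radius: 0.6 (r-2)^2 - 0.02 = 0.8 (r-2.6)^2
  r_seam <- polyroot(c(0.6 * 4 - 0.8 * 6.76 - 0.02, -0.6 * 4 + 0.8 * 5.2, -0.2))
  r_star <- min(Re(r_seam[abs(Im(r_seam)) < 1e-9]))
  cfg <- opt_config(mode = "spin", project_rigid = TRUE, trust_radius_init = 0.2)
  q0 <- c(0, 0, 0, 2.1, 0.3, -0.2)
  res0 <- optimize_mecp(mk_backend(c(0, 0, 0)), q0, cfg)
  expect_true(res0$converged)
  d0 <- sqrt(sum((res0$q[1:3] - res0$q[4:6])^2))
  expect_equal(d0, r_star, tolerance = 1e-5)
  shift <- c(1.5, -2.0, 0.7)
  res1 <- optimize_mecp(mk_backend(shift), q0 + rep(shift, 2), cfg)
  expect_true(res1$converged)
  expect_equal(res1$q, res0$q + rep(shift, 2), tolerance = 1e-6)
})
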
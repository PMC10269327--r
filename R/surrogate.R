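# Pseudodiabatic surrogate: three GEK surfaces (alpha, beta, gamma) fitted to
# the diabatized optimization history, or two (alpha, beta) for different-spin
# crossings where gamma is identically zero. The adiabatic quantities are
# recovered by diagonalizing the 2x2 diabatic Hamiltonian at the query.

#' Build the pseudodiabatic surrogate from an optimization history
#'
#' The history is diabatized against a gauge built from its last point, then
#' one GEK surface is fitted per diabatic quantity, all sharing the same
#' characteristic lengths. Baselines follow the standard policy: `mu_alpha`
#' and `mu_beta` are `mu_offset` (default 10 hartree) above the maximum of the
#' respective surface's data, and `mu_gamma = 0`. By construction the
#' surrogate reproduces every history point's `E_A`, `E_B`, `s`, `g` and
#' (up to the recorded sign) `h`.
#'
#' To keep the covariance solve well conditioned as optimizer points cluster,
#' only the most recent `max_data` points are used and near-duplicate
#' geometries (scaled distance below `dedup_tol`) are dropped in favour of the
#' later point.
#'
#' @param history list of [adiabatic_point()]s, oldest first.
#' @param mode `"ci"` (three surfaces) or `"spin"` (two, no coupling).
#' @param lengths characteristic lengths (bohr), e.g. from
#'   [lengths_from_hessian()].
#' @param nugget GEK nugget.
#' @param mu_offset baseline elevation for the energy surfaces (hartree).
#' @param max_data number of most recent points retained.
#' @param dedup_tol scaled-distance threshold for duplicate removal.
#' @return an object of class `pd_surrogate`.
#' @export
build_surrogate <- function(history, mode = c("ci", "spin"), lengths,
                            nugget = 1e-10, mu_offset = 10, max_data = 20,
                            dedup_tol = 1e-7) {
  mode <- match.arg(mode)
  stopifnot(length(history) >= 1)
  m <- length(history[[1]]$q)
  stopifnot(length(lengths) == m, all(lengths > 0))
  if (length(history) > max_data) {
    history <- history[seq(length(history) - max_data + 1, length(history))]
  }
  # drop near-duplicates, keeping the most recent occurrence
  keep <- rep(TRUE, length(history))
  for (i in seq_along(history)) {
    if (!keep[i]) next
    for (j in seq_along(history)) {
      if (j <= i || !keep[j]) next
      dsc <- sqrt(sum(((history[[i]]$q - history[[j]]$q) / lengths)^2))
      if (dsc < dedup_tol) { keep[i] <- FALSE; break }
    }
  }
  history <- history[keep]
  diab <- diabatize_history(history, mode)
  dp <- diab$points
  qs <- do.call(rbind, lapply(dp, `[[`, "q"))
  mk <- function(field, gfield) {
    gek_dataset(qs, vapply(dp, `[[`, numeric(1), field),
                do.call(rbind, lapply(dp, `[[`, gfield)))
  }
  ds_a <- mk("alpha", "grad_alpha")
  ds_b <- mk("beta", "grad_beta")
  mu_a <- max(ds_a$values) + mu_offset
  mu_b <- max(ds_b$values) + mu_offset
  surfaces <- list(alpha = fit_gek(ds_a, mu_a, lengths, nugget),
                   beta = fit_gek(ds_b, mu_b, lengths, nugget))
  mu <- list(alpha = mu_a, beta = mu_b)
  if (mode == "ci") {
    ds_g <- mk("gamma", "grad_gamma")
    surfaces$gamma <- fit_gek(ds_g, 0, lengths, nugget)
    mu$gamma <- 0
  }
  structure(list(mode = mode, surfaces = surfaces, gauge = diab$gauge,
                 mu = mu, lengths = as.numeric(lengths),
                 diabatic = dp, history = history),
            class = "pd_surrogate")
}

#' Evaluate adiabatic quantities on the surrogate
#'
#' Predicts `alpha`, `beta` (and `gamma` in `ci` mode) with their gradients,
#' then diagonalizes the 2x2 diabatic Hamiltonian to return adiabatic data.
#' In spin mode no diagonalization is needed (`E_A`, `E_B` are the ordered
#' `alpha`, `beta` predictions and the coupling is undefined). The maximum of
#' the component surfaces' predicted variances is returned for step
#' restriction.
#'
#' @param surrogate a `pd_surrogate`.
#' @param q query geometry (bohr).
#' @return list with `point` (an [adiabatic_point()]), `diabatic` (the raw
#'   predictions: `alpha`, `beta`, `gamma`, `delta`, `tau` and gradients) and
#'   `variance_max`.
#' @export
evaluate_adiabatic <- function(surrogate, q) {
  stopifnot(inherits(surrogate, "pd_surrogate"))
  q <- as.numeric(q)
  pa <- predict(surrogate$surfaces$alpha, q)
  pb <- predict(surrogate$surfaces$beta, q)
  if (surrogate$mode == "spin") {
    vr <- max(pa$variance, pb$variance)
    diab <- list(alpha = pa$value, beta = pb$value, gamma = 0,
                 delta = (pa$value - pb$value) / 2,
                 tau = (pa$value + pb$value) / 2,
                 grad_alpha = pa$gradient, grad_beta = pb$gradient,
                 grad_gamma = numeric(length(q)),
                 grad_delta = (pa$gradient - pb$gradient) / 2,
                 grad_tau = (pa$gradient + pb$gradient) / 2)
    pt <- adiabatic_point(q = q, E_A = pa$value, E_B = pb$value,
                          s = diab$grad_tau, g = diab$grad_delta,
                          h_defined = FALSE,
                          degenerate = abs(diab$delta) < 1e-9)
    return(list(point = pt, diabatic = diab, variance_max = vr))
  }
  pg <- predict(surrogate$surfaces$gamma, q)
  d <- diabatic_point(q = q, alpha = pa$value, beta = pb$value,
                      gamma = pg$value, grad_alpha = pa$gradient,
                      grad_beta = pb$gradient, grad_gamma = pg$gradient)
  pt <- adiabatic_from_diabatic(d)
  diab <- list(alpha = pa$value, beta = pb$value, gamma = pg$value,
               delta = (pa$value - pb$value) / 2,
               tau = (pa$value + pb$value) / 2,
               grad_alpha = pa$gradient, grad_beta = pb$gradient,
               grad_gamma = pg$gradient,
               grad_delta = (pa$gradient - pb$gradient) / 2,
               grad_tau = (pa$gradient + pb$gradient) / 2)
  list(point = pt, diabatic = diab,
       variance_max = max(pa$variance, pb$variance, pg$variance))
}

#' Maximum predicted variance at a geometry
#' @param surrogate a `pd_surrogate`.
#' @param q query geometry.
#' @return largest component-surface variance.
#' @export
surrogate_variance <- function(surrogate, q) {
  vs <- vapply(surrogate$surfaces, function(s) predict(s, q)$variance,
               numeric(1))
  max(vs)
}

#' Serialize a surrogate snapshot to JSON
#'
#' Writes geometries, diabatic data, GEK weights, baselines and the gauge to
#' a JSON file for debugging and plotting.
#'
#' @param surrogate a `pd_surrogate`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_surrogate_snapshot <- function(surrogate, path) {
  dp <- surrogate$diabatic
  snap <- list(
    mode = surrogate$mode,
    lengths = surrogate$lengths,
    mu = surrogate$mu,
    gauge = if (is.null(surrogate$gauge)) NULL else
      list(q_ref = surrogate$gauge$q_ref, k_delta = surrogate$gauge$k_delta,
           k_gamma = surrogate$gauge$k_gamma),
    points = lapply(dp, function(p) list(
      q = p$q, alpha = p$alpha, beta = p$beta, gamma = p$gamma,
      grad_alpha = p$grad_alpha, grad_beta = p$grad_beta,
      grad_gamma = p$grad_gamma, omega = p$omega, h_flipped = p$h_flipped)),
    weights = lapply(surrogate$surfaces, `[[`, "weights"))
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pd_surrogate <- function(x, ...) {
  cat(sprintf("<pd_surrogate> mode=%s  n=%d points  m=%d dims\n",
              x$mode, length(x$history), length(x$history[[1]]$q)))
  invisible(x)
}
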
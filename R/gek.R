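# Gradient-enhanced Kriging with a Matern-5/2 kernel and analytic
# derivatives. The kernel is unscaled (unit prior variance); a constant trend
# mu absorbs the energy offset. With t = sqrt(5) d and
# d^2 = sum_k ((q_k - q'_k)/l_k)^2:
#
#   f(d)                 = (1 + t + t^2/3) exp(-t)
#   df/dq'_k             = (5/3)(1 + t) exp(-t) r_k / l_k^2,   r = q - q'
#   d^2f/dq_j dq'_k      = -(25/3) exp(-t) r_j r_k / (l_j^2 l_k^2)
#                          + (5/3)(1 + t) exp(-t) delta_jk / l_k^2
#
# All three are smooth at d = 0 (the apparent sqrt singularity cancels), which
# is what makes the Matern-5/2 family usable with gradient data.

#' Matern-5/2 kernel and its derivatives
#'
#' @param q,q_prime geometries (numeric vectors of equal length).
#' @param lengths positive characteristic lengths, one per dimension (bohr).
#' @param order 0 for the kernel value, 1 for the gradient with respect to the
#'   components of `q_prime`, 2 for the mixed second-derivative block
#'   `d2 f / dq dq'` (m x m, rows index `q`, columns `q_prime`).
#' @return scalar, vector, or matrix according to `order`.
#' @export
kernel_matern52 <- function(q, q_prime, lengths, order = 0) {
  stopifnot(all(lengths > 0), length(q) == length(q_prime))
  r <- as.numeric(q) - as.numeric(q_prime)
  il2 <- 1 / lengths^2
  t5 <- sqrt(5 * sum(r^2 * il2))
  e <- exp(-t5)
  if (order == 0) return((1 + t5 + t5^2 / 3) * e)
  if (order == 1) return((5 / 3) * (1 + t5) * e * r * il2)
  if (order == 2) {
    rs <- r * il2
    return(-(25 / 3) * e * outer(rs, rs) + diag((5 / 3) * (1 + t5) * e * il2,
                                                nrow = length(r)))
  }
  stop("kernel_matern52: order must be 0, 1 or 2")
}

#' Dataset for a gradient-enhanced Kriging fit
#'
#' Holds `n` sample points in `m` dimensions, each with a value and a full
#' gradient: `n (m + 1)` independent data. Points must be pairwise distinct
#' on the scale of the characteristic lengths that will be used for the fit.
#'
#' @param q matrix `n x m` of geometries (rows) or a list of vectors.
#' @param values numeric vector of length `n`.
#' @param gradients matrix `n x m` (rows are gradients) or list of vectors.
#' @return an object of class `gek_dataset`.
#' @export
gek_dataset <- function(q, values, gradients) {
  if (is.list(q)) q <- do.call(rbind, q)
  if (is.list(gradients)) gradients <- do.call(rbind, gradients)
  q <- as.matrix(q); gradients <- as.matrix(gradients)
  n <- nrow(q); m <- ncol(q)
  stopifnot(length(values) == n, nrow(gradients) == n, ncol(gradients) == m)
  structure(list(q = unname(q), values = as.numeric(values),
                 gradients = unname(gradients), n = n, m = m),
            class = "gek_dataset")
}

#' Characteristic lengths from a diagonal approximate Hessian
#'
#' Chooses per-dimension lengths so that a single-point GEK surface with
#' baseline `mu = E + mu_offset` has, at its data point, the Hessian
#' `diag(hessian_diag)`. The analytic second derivative of the Matern-5/2
#' kernel at zero distance gives curvature `mu_offset * 5 / (3 l_k^2)` along
#' dimension `k`, hence `l_k = sqrt(5 mu_offset / (3 H_kk))`. Non-positive
#' Hessian entries are floored at `min_curvature`.
#'
#' @param hessian_diag diagonal of an approximate Hessian (hartree/bohr^2).
#' @param mu_offset baseline elevation above the data (hartree, default 10).
#' @param min_curvature floor for non-positive entries (hartree/bohr^2).
#' @return vector of characteristic lengths (bohr).
#' @export
lengths_from_hessian <- function(hessian_diag, mu_offset = 10,
                                 min_curvature = 0.025) {
  hd <- pmax(as.numeric(hessian_diag), min_curvature)
  sqrt(5 * mu_offset / (3 * hd))
}

# Covariance block between data at q_i and data at q_j:
# [[ f,            (df/dq_j)^T ],
#  [ df/dq_i,      d2f/dq_i dq_j ]]
.gek_block <- function(qi, qj, lengths) {
  f0 <- kernel_matern52(qi, qj, lengths, 0)
  d1 <- kernel_matern52(qi, qj, lengths, 1) # d/dq_j
  d2 <- kernel_matern52(qi, qj, lengths, 2) # d2/dq_i dq_j
  rbind(c(f0, d1), cbind(-d1, d2))
}

#' Fit a gradient-enhanced Kriging surface
#'
#' Solves `M w = y` where `M` is the full value/gradient covariance matrix
#' (with a small nugget on the diagonal for positive definiteness) and `y`
#' stacks, per point, the value minus `mu` followed by the `m` gradient
#' components, in history order. The resulting surface interpolates values and
#' gradients at all data points to close to machine precision.
#'
#' @param dataset a [gek_dataset()].
#' @param mu constant trend baseline (hartree).
#' @param lengths characteristic lengths (bohr), length `m`.
#' @param nugget diagonal regularization relative to the unit prior variance.
#' @return an object of class `gek_surface`.
#' @export
fit_gek <- function(dataset, mu, lengths, nugget = 1e-10) {
  stopifnot(inherits(dataset, "gek_dataset"), length(lengths) == dataset$m,
            all(lengths > 0))
  n <- dataset$n; m <- dataset$m; b <- m + 1
  if (n > 1) {
    ds <- as.matrix(stats::dist(sweep(dataset$q, 2, lengths, "/")))
    diag(ds) <- Inf
    if (min(ds) < 1e-8) {
      ij <- arrayInd(which.min(ds), dim(ds))
      stop(sprintf(
        "fit_gek: dataset violates the distinctness invariant; closest points are %d and %d (scaled distance %.3e)",
        min(ij), max(ij), min(ds)))
    }
  }
  M <- matrix(0, n * b, n * b)
  for (i in seq_len(n)) {
    for (j in i:n) {
      blk <- .gek_block(dataset$q[i, ], dataset$q[j, ], lengths)
      ri <- (i - 1) * b + seq_len(b); rj <- (j - 1) * b + seq_len(b)
      M[ri, rj] <- blk
      if (j > i) M[rj, ri] <- t(blk)
    }
  }
  y <- as.numeric(t(cbind(dataset$values - mu, dataset$gradients)))
  fit <- NULL
  for (nug in nugget * c(1, 1e2, 1e4)) {
    ch <- tryCatch(chol(M + diag(nug, n * b)), error = function(e) NULL)
    if (!is.null(ch)) { fit <- list(chol = ch, nugget = nug); break }
  }
  if (is.null(fit)) {
    ds <- as.matrix(stats::dist(sweep(dataset$q, 2, lengths, "/")))
    diag(ds) <- Inf
    ij <- arrayInd(which.min(ds), dim(ds))
    stop(sprintf(
      "fit_gek: covariance matrix not positive definite beyond nugget rescue; closest points are %d and %d (scaled distance %.3e)",
      ij[1], ij[2], min(ds)))
  }
  solve_chol <- function(rhs) {
    backsolve(fit$chol, backsolve(fit$chol, rhs, transpose = TRUE))
  }
  # iterative refinement against the unregularized matrix: the nugget keeps
  # the factorization stable while the refined weights interpolate the data
  # to close to machine precision
  w <- solve_chol(y)
  yscale <- max(abs(y), 1e-300)
  for (it in 1:5) {
    r <- y - as.numeric(M %*% w)
    if (max(abs(r)) <= 1e-14 * yscale) break
    w <- w + solve_chol(r)
  }
  structure(list(dataset = dataset, mu = mu, lengths = as.numeric(lengths),
                 weights = as.numeric(w), chol = fit$chol, nugget = fit$nugget),
            class = "gek_surface")
}

# Kernel vector between a query q and the dataset (values + gradients).
.gek_v <- function(surface, q) {
  d <- surface$dataset; b <- d$m + 1
  v <- numeric(d$n * b)
  for (i in seq_len(d$n)) {
    qi <- d$q[i, ]
    v[(i - 1) * b + 1] <- kernel_matern52(q, qi, surface$lengths, 0)
    v[(i - 1) * b + 1 + seq_len(d$m)] <- kernel_matern52(q, qi, surface$lengths, 1)
  }
  v
}

#' Predict value, gradient and variance from a GEK surface
#'
#' `value = mu + v . w`; the gradient is the analytic derivative of that
#' expression; the variance is the simple-kriging predicted variance
#' `1 - v^T M^{-1} v` (unit prior variance), clamped at zero. The variance
#' vanishes (up to the nugget scale) at data points and approaches 1 far from
#' all data.
#'
#' @param object a fitted `gek_surface`.
#' @param q query geometry.
#' @param ... unused.
#' @return list with `value`, `gradient`, `variance`.
#' @export
predict.gek_surface <- function(object, q, ...) {
  d <- object$dataset; m <- d$m; b <- m + 1
  q <- as.numeric(q)
  v <- .gek_v(object, q)
  grad <- numeric(m)
  for (i in seq_len(d$n)) {
    qi <- d$q[i, ]
    idx <- (i - 1) * b
    # d/dq of f(q, q_i) is minus the order-1 derivative (which is wrt q')
    grad <- grad - kernel_matern52(q, qi, object$lengths, 1) * object$weights[idx + 1]
    d2 <- kernel_matern52(q, qi, object$lengths, 2)
    grad <- grad + d2 %*% object$weights[idx + 1 + seq_len(m)]
  }
  z <- backsolve(object$chol, v, transpose = TRUE)
  structure(list(value = object$mu + sum(v * object$weights),
                 gradient = as.numeric(grad),
                 variance = max(0, 1 - sum(z^2))), class = "gek_prediction")
}

#' @export
print.gek_surface <- function(x, ...) {
  cat(sprintf("<gek_surface> n=%d points, m=%d dims, mu=%.4f, nugget=%.1e\n",
              x$dataset$n, x$dataset$m, x$mu, x$nugget))
  invisible(x)
}
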
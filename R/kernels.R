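# Temporal correlation kernel and likelihood building blocks.
#
# Within a subject the correlation between observations at times t_j, t_k is
# exp(-tau * |t_j - t_k|): an Ornstein-Uhlenbeck / AR(1) kernel on an
# irregular grid. Its inverse is tridiagonal (Markov property), which every
# likelihood computation below exploits.

# optimization/sampling domain for the dampening rate tau; the lower bound
# keeps Phi away from its singular all-ones limit at tau = 0
TAU_MIN <- 1e-4
TAU_MAX <- 1e4

#' Temporal correlation matrix
#'
#' Builds the within-subject correlation matrix
#' `Phi[j, k] = exp(-tau * |t_j - t_k|)` for a strictly increasing vector of
#' observation times. `tau = Inf` gives the identity (independence).
#'
#' @param tau positive dampening rate (larger = faster decay).
#' @param times strictly increasing, finite observation times.
#' @return symmetric positive-definite matrix with unit diagonal.
#' @export
build_phi <- function(tau, times) {
  check_tau_times(tau, times)
  if (is.infinite(tau)) return(diag(length(times)))
  exp(-tau * abs(outer(times, times, "-")))
}

check_tau_times <- function(tau, times) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("tau must be a positive scalar")
  }
  if (any(!is.finite(times))) stop("non-finite observation times")
  if (length(times) > 1L && is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  invisible(TRUE)
}

# Tridiagonal inverse of the exponential kernel on an irregular grid.
# With rho_k = exp(-tau * (t_{k+1} - t_k)):
#   off-diagonal  b_k = -rho_k / (1 - rho_k^2)
#   diagonal      a_j = 1 + rho_{j-1}^2/(1-rho_{j-1}^2) + rho_j^2/(1-rho_j^2)
#   log|Phi|          = sum_k log(1 - rho_k^2)
# Returns the band representation; phi_inverse() assembles the dense matrix.
phi_inverse_bands <- function(tau, times) {
  check_tau_times(tau, times)
  n <- length(times)
  if (n == 1L) return(list(diag = 1, offdiag = numeric(0), logdet = 0))
  rho <- if (is.infinite(tau)) rep(0, n - 1L) else exp(-tau * diff(times))
  r2 <- rho^2
  f <- r2 / (1 - r2)
  a <- 1 + c(0, f) + c(f, 0)
  list(diag = a, offdiag = -rho / (1 - r2), logdet = sum(log1p(-r2)))
}

#' Inverse and log-determinant of the temporal correlation matrix
#'
#' Exploits the Markov property of the exponential kernel: the inverse is
#' tridiagonal and the log-determinant is `sum(log(1 - rho_k^2))` with
#' `rho_k = exp(-tau * (t_{k+1} - t_k))`.
#'
#' @inheritParams build_phi
#' @return list with `inverse` (dense matrix) and `logdet`.
#' @export
phi_inverse <- function(tau, times) {
  bd <- phi_inverse_bands(tau, times)
  n <- length(bd$diag)
  M <- diag(bd$diag, n)
  if (n > 1L) {
    idx <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
    M[idx] <- bd$offdiag
    M[idx[, 2:1, drop = FALSE]] <- bd$offdiag
  }
  list(inverse = M, logdet = bd$logdet)
}

#' Per-subject weighted second-moment matrix S_i(tau)
#'
#' Computes `S_i(tau) = sum_jk phi^-_jk y_k y_j'`, the `p x p` matrix through
#' which a subject's contribution to the likelihood enters as
#' `tr(S_i(tau) Omega) = y_i' (Phi_i^-1 kron Omega) y_i`.
#'
#' @param tau positive dampening rate.
#' @param block a subject block (list with `times` and `values`).
#' @return symmetric `p x p` matrix.
#' @export
s_matrix <- function(tau, block) {
  bd <- phi_inverse_bands(tau, block$times)
  s_matrix_bands(bd$diag, bd$offdiag, block$values)
}

# assemble Y' Phi^-1 Y from the tridiagonal bands of Phi^-1
s_matrix_bands <- function(a, b, Y) {
  n <- nrow(Y)
  AY <- Y * a
  if (n > 1L) {
    AY[-n, ] <- AY[-n, , drop = FALSE] + b * Y[-1L, , drop = FALSE]
    AY[-1L, ] <- AY[-1L, , drop = FALSE] + b * Y[-n, , drop = FALSE]
  }
  S <- crossprod(Y, AY)
  0.5 * (S + t(S))
}

#' Pooled weighted second-moment matrix
#'
#' `Sbar(tau) = (1/n) * sum_i S_i(tau_i)` over all subjects, the matrix the
#' graphical-lasso subproblem treats as an empirical covariance.
#'
#' @param tau a positive scalar (shared rate) or a length-`m` vector of
#'   per-subject rates.
#' @param data a [longitudinal_data] object.
#' @return symmetric `p x p` matrix.
#' @export
sbar <- function(tau, data) {
  stopifnot(inherits(data, "longitudinal_data"), data$m >= 1L)
  tau <- rep_len(tau, data$m)
  S <- matrix(0, data$p, data$p)
  for (i in seq_len(data$m)) S <- S + s_matrix(tau[i], data$subjects[[i]])
  S / data$n
}

#' Log-likelihood of the homogeneous model
#'
#' Evaluates, up to the additive constant `-(n*p/2)*log(2*pi)`, the Gaussian
#' log-likelihood of the stacked data under shared dampening rate `tau`:
#' `-(1/2) * (sum_i p*log|Phi_i| - n*log|Omega| + n*tr(Sbar(tau) Omega))`.
#'
#' @param omega `p x p` positive-definite precision matrix.
#' @param tau positive dampening rate shared by all subjects.
#' @param data a [longitudinal_data] object.
#' @return scalar log-likelihood (constant-adjusted).
#' @export
loglik_homogeneous <- function(omega, tau, data) {
  stopifnot(inherits(data, "longitudinal_data"))
  ld_phi <- 0
  tr_term <- 0
  for (b in data$subjects) {
    bd <- phi_inverse_bands(tau, b$times)
    ld_phi <- ld_phi + bd$logdet
    tr_term <- tr_term + sum(s_matrix_bands(bd$diag, bd$offdiag, b$values) * omega)
  }
  ld_omega <- determinant(omega, logarithm = TRUE)
  if (ld_omega$sign <= 0) stop("omega must be positive definite")
  -0.5 * (data$p * ld_phi - data$n * as.numeric(ld_omega$modulus) + tr_term)
}

# Quadratic-form cache for one subject: C[j,k] = y_j' Omega y_k (n_i x n_i).
# Given C, the quadratic form y'(Phi^-1 kron Omega)y at any tau is
# sum(a * diag(C)) + 2 * sum(b * superdiag(C)) -- O(n_i) per tau.
quadform_cache <- function(block, omega) {
  C <- block$values %*% omega %*% t(block$values)
  n <- nrow(C)
  list(d = diag(C),
       o = if (n > 1L) C[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] else numeric(0),
       dt = diff(block$times), n = n)
}

# Vectorized over a grid of tau values: returns for each tau the
# log-determinant of Phi and the quadratic form y'(Phi^-1 kron Omega)y,
# plus (optionally) the tridiagonal coefficient matrices for E[S_i].
quadform_grid <- function(cache, tau_grid, keep_bands = FALSE) {
  ng <- length(tau_grid)
  if (cache$n == 1L) {
    out <- list(logdet = rep(0, ng), quad = rep(cache$d, ng))
    if (keep_bands) {
      out$A <- matrix(1, ng, 1L)
      out$B <- matrix(0, ng, 0L)
    }
    return(out)
  }
  rho <- exp(-outer(tau_grid, cache$dt))      # ng x (n-1)
  r2 <- rho^2
  f <- r2 / (1 - r2)
  A <- 1 + cbind(0, f) + cbind(f, 0)          # ng x n
  B <- -rho / (1 - r2)                        # ng x (n-1)
  out <- list(logdet = rowSums(log1p(-r2)),
              quad = drop(A %*% cache$d + 2 * (B %*% cache$o)))
  if (keep_bands) { out$A <- A; out$B <- B }
  out
}

#' Unnormalized log posterior density of a subject's dampening rate
#'
#' Under the heterogeneous (or covariate-adjusted) model the subject-level
#' rate `tau_i` has an exponential prior with rate `alpha_i`; its conditional
#' log density given the subject's data is, up to a constant,
#' `-(p/2)*log|Phi_i(tau)| - y_i'(Phi_i^-1 kron Omega)y_i / 2 - alpha_i*tau`.
#'
#' @param tau positive rate value(s) at which to evaluate (vectorized).
#' @param block a subject block.
#' @param omega positive-definite precision matrix.
#' @param alpha_i positive prior rate for this subject.
#' @return vector of unnormalized log densities.
#' @export
tau_posterior_logdensity <- function(tau, block, omega, alpha_i) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (alpha_i <= 0) stop("alpha_i must be positive")
  p <- ncol(block$values)
  cache <- quadform_cache(block, omega)
  g <- quadform_grid(cache, tau)
  -(p / 2) * g$logdet - g$quad / 2 - alpha_i * tau
}
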
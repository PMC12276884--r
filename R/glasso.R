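#' Graphical lasso subproblem
#'
#' Solves `min_{Omega > 0} -log|Omega| + tr(S Omega) + lambda * ||Omega||_1`
#' by blockwise coordinate descent. This is the inner building block every
#' solver calls with a (weighted) second-moment matrix in place of `S`.
#'
#' @param S symmetric `p x p` matrix.
#' @param lambda nonnegative penalty.
#' @param penalize_diag if `TRUE` the L1 penalty covers the diagonal too,
#'   so `diag(W) = diag(S) + lambda`; default `FALSE` (off-diagonal-only
#'   penalty, which keeps the scale of the precision diagonal anchored to
#'   the data).
#' @param tol convergence tolerance, relative to the average absolute
#'   off-diagonal entry of `S`.
#' @param max_iter maximum outer sweeps.
#' @param warm optional list with `w` and `b` from a previous solution
#'   (warm start along a path).
#' @return list with `omega` (precision estimate, symmetric), `w`
#'   (estimated covariance), `b` (lasso coefficients), `iterations`,
#'   `converged`.
#' @export
glasso_fit <- function(S, lambda, penalize_diag = FALSE, tol = 1e-4,
                       max_iter = 50L, warm = NULL) {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("S must be symmetric")
  }
  if (lambda < 0) stop("lambda must be nonnegative")
  if (any(diag(S) + (if (penalize_diag) lambda else 0) <= 0)) {
    stop("diag(S) + lambda must be positive")
  }
  # retry ladder for ill-conditioned inputs: cold start, growing diagonal
  # ridge, tightening tolerance
  ridges <- c(0, 1e-6, 1e-4, 1e-2) * mean(diag(S))
  tols <- c(tol, tol / 10, tol / 10, tol / 100)
  for (attempt in seq_along(ridges)) {
    Sr <- S
    if (ridges[attempt] > 0) diag(Sr) <- diag(Sr) + ridges[attempt]
    res <- glasso_cpp(Sr, lambda, penalize_diag, tols[attempt],
                      as.integer(max_iter),
                      if (is.null(warm)) NULL else warm$w,
                      if (attempt == 1 && !is.null(warm)) warm$b else NULL)
    ok <- all(is.finite(res$omega)) &&
      determinant(res$omega, logarithm = TRUE)$sign > 0 &&
      all(diag(res$omega) > 0)
    if (ok) break
  }
  if (!ok) stop("graphical lasso failed: non-positive-definite solution")
  if (!res$converged) {
    warning("graphical lasso did not converge in ", max_iter,
            " sweeps; returning best iterate")
  }
  res
}

# penalized objective of the subproblem, used in tests and descent checks
glasso_objective <- function(omega, S, lambda, penalize_diag = FALSE) {
  ld <- determinant(omega, logarithm = TRUE)
  pen <- if (penalize_diag) sum(abs(omega)) else sum(abs(omega)) - sum(abs(diag(omega)))
  -as.numeric(ld$modulus) + sum(S * omega) + lambda * pen
}

# default lambda grid: log-spaced from the smallest lambda that gives an
# empty graph down to ratio * lambda_max
default_lambda_grid <- function(S, nlambda = 15L, lambda_min_ratio = 0.05) {
  off <- abs(S)
  diag(off) <- 0
  lmax <- max(off)
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}
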
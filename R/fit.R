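#' Fit a stationary Gaussian graphical model to longitudinal data
#'
#' Estimates a sparse precision matrix (microbial interaction network) from
#' irregularly spaced longitudinal abundance data by L1-penalized maximum
#' likelihood, jointly with the temporal dampening structure:
#'
#' * `model = "homogeneous"`: one dampening rate `tau` shared by all
#'   subjects; block coordinate descent alternates the graphical lasso on
#'   the weighted second-moment matrix `Sbar(tau)` with 1-D likelihood
#'   maximization over `tau`.
#' * `model = "heterogeneous"`: subject-level rates `tau_i ~ Exp(alpha)`
#'   treated as missing data; Monte-Carlo EM alternates posterior sampling
#'   of the `tau_i`, the closed-form update `alpha = m / sum(E[tau_i])`,
#'   and a graphical-lasso update of the network.
#' * `model = "covariate"`: prior rates `alpha_i = exp(alpha' x_i)` depend
#'   log-linearly on per-subject covariates; as above but the M-step for
#'   the coefficient vector is solved by BFGS (with Newton polish) on its
#'   smooth convex objective.
#'
#' @param data a [longitudinal_data] object.
#' @param lambda nonnegative L1 penalty on the precision matrix.
#' @param model which dampening model to fit.
#' @param covariates optional covariate table (see [set_covariates]);
#'   required for `model = "covariate"` unless `data` already carries
#'   covariates.
#' @param tau_init initial shared dampening rate (homogeneous model).
#' @param alpha_init initial prior rate for the subject-level rates
#'   (heterogeneous/covariate models); default `1/0.1`.
#' @param h Monte-Carlo sample size per subject per E-step; the final
#'   refinement E-step uses `10 * h`.
#' @param tol stopping tolerance on the dampening parameter and on the
#'   max-norm change of the precision matrix.
#' @param max_outer maximum outer iterations.
#' @param penalize_diag whether the L1 penalty covers the diagonal.
#' @param seed optional integer seed set before any Monte-Carlo sampling.
#' @param edge_threshold entries of the fitted precision matrix with
#'   absolute value above this count as edges.
#' @return an object of class `"sggm"`; see Details. Key elements:
#'   `omega` (fitted precision matrix), `tau` or `alpha`/`coefficients`,
#'   `tau_i` (per-subject posterior-mean dampening forecasts, latent
#'   models only), `loglik` (unpenalized log-likelihood; a documented
#'   EM surrogate for the latent models), `n_edges`, `converged`.
#' @examples
#' sim <- simulate_sggm(p = 8, m = 6, mean_ni = 6, edge_density = 0.2,
#'                      scenario = "homogeneous", tau = 0.1, seed = 1)
#' fit <- sggm(sim$data, lambda = 0.3)
#' fit
#' @export
sggm <- function(data, lambda,
                 model = c("homogeneous", "heterogeneous", "covariate"),
                 covariates = NULL, tau_init = 0.1, alpha_init = 1 / 0.1,
                 h = 500L, tol = 1e-3, max_outer = 30L,
                 penalize_diag = FALSE, seed = NULL, edge_threshold = 1e-8) {
  model <- match.arg(model)
  stopifnot(inherits(data, "longitudinal_data"))
  if (data$p < 2L) stop("need at least two taxa")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(covariates)) data <- set_covariates(data, covariates)

  fit <- switch(model,
    homogeneous = fit_homogeneous(data, lambda, tau_init = tau_init,
                                  tol = tol, max_outer = max_outer,
                                  penalize_diag = penalize_diag),
    heterogeneous = fit_mcem(data, lambda, X = NULL, alpha_init = alpha_init,
                             h = h, tol = tol, max_outer = max_outer,
                             penalize_diag = penalize_diag),
    covariate = {
      X <- design_matrix(data)
      if (ncol(X) < 2L && is.null(covariates)) {
        stop("covariate model needs per-subject covariates; ",
             "use set_covariates() or the 'covariates' argument")
      }
      fit_mcem(data, lambda, X = X, alpha_init = alpha_init, h = h,
               tol = tol, max_outer = max_outer,
               penalize_diag = penalize_diag)
    })

  fit$model <- model
  fit$edge_threshold <- edge_threshold
  fit$n_edges <- count_edges(fit$omega, edge_threshold)
  fit$taxon_names <- data$taxon_names
  dimnames(fit$omega) <- list(data$taxon_names, data$taxon_names)
  fit$n <- data$n; fit$p <- data$p; fit$m <- data$m
  fit$call <- match.call()
  class(fit) <- "sggm"
  fit
}

count_edges <- function(omega, threshold = 1e-8) {
  sum(abs(omega[upper.tri(omega)]) > threshold)
}

# ---- homogeneous solver (block coordinate descent) -------------------------

fit_homogeneous <- function(data, lambda, tau_init = 0.1, tol = 1e-3,
                            max_outer = 50L, penalize_diag = FALSE,
                            gl_tol = 1e-4, warm = NULL) {
  ni <- vapply(data$subjects, function(b) length(b$times), integer(1L))
  tau0 <- if (!is.null(warm$tau)) warm$tau else tau_init

  if (all(ni == 1L)) {
    # Phi_i = 1 for every subject: tau carries no information and the model
    # reduces to an independent-data graphical lasso on the empirical
    # second-moment matrix
    warning("all subjects have a single observation: ",
            "dampening rate is unidentifiable, returning plain graphical lasso")
    gl <- glasso_fit(sbar(tau0, data), lambda, penalize_diag, gl_tol,
                     warm = warm$gl)
    ll <- loglik_homogeneous(gl$omega, tau0, data)
    return(list(omega = gl$omega, tau = tau0, tau_i = NULL, lambda = lambda,
                loglik = ll,
                penalized_objective = -2 * ll + data$n * lambda *
                  l1_norm(gl$omega, penalize_diag),
                iterations = 0L, converged = TRUE, objective_trace = numeric(0),
                gl_state = list(w = gl$w, b = gl$b), penalize_diag = penalize_diag))
  }

  gl_state <- warm$gl
  omega0 <- NULL
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    gl <- glasso_fit(sbar(tau0, data), lambda, penalize_diag, gl_tol,
                     warm = gl_state)
    gl_state <- list(w = gl$w, b = gl$b)
    omega <- gl$omega
    tau <- optimize_tau(omega, data, tau0)
    trace <- c(trace, -2 * loglik_homogeneous(omega, tau, data) +
                 data$n * lambda * l1_norm(omega, penalize_diag))
    if (!is.null(omega0) &&
        abs(tau - tau0) < tol && max(abs(omega - omega0)) < tol) {
      converged <- TRUE
      tau0 <- tau; omega0 <- omega
      break
    }
    if (it >= max_outer) { tau0 <- tau; omega0 <- omega; break }
    tau0 <- tau; omega0 <- omega
  }

  ll <- loglik_homogeneous(omega0, tau0, data)
  list(omega = omega0, tau = tau0, tau_i = NULL, lambda = lambda,
       sbar_hat = sbar(tau0, data), loglik = ll,
       penalized_objective = -2 * ll + data$n * lambda *
         l1_norm(omega0, penalize_diag),
       iterations = it, converged = converged, objective_trace = trace,
       gl_state = gl_state, penalize_diag = penalize_diag)
}

l1_norm <- function(omega, penalize_diag = FALSE) {
  if (penalize_diag) sum(abs(omega)) else sum(abs(omega)) - sum(abs(diag(omega)))
}

#' Maximize the homogeneous likelihood over the dampening rate
#'
#' One-dimensional bounded maximization (Brent on the log scale) of the
#' homogeneous log-likelihood in `tau` for fixed `omega`. In the spirit of
#' a Newton step from the current iterate, the search is local: one decade
#' each way around `tau_init` (intersected with `[1e-4, 1e4]`). A global
#' search is deliberately avoided — for strongly correlated
#' high-dimensional data the joint penalized objective is unbounded along
#' `tau -> 0`, and the useful estimate is the local maximizer the
#' alternating algorithm tracks.
#'
#' With a single observation per subject the likelihood is flat in `tau`
#' and `tau_init` is returned with a warning.
#'
#' @param omega positive-definite precision matrix.
#' @param data a [longitudinal_data] object.
#' @param tau_init current iterate / fallback value.
#' @param span half-width of the search interval in decades.
#' @return the maximizing `tau`.
#' @export
optimize_tau <- function(omega, data, tau_init = 0.1, span = 1) {
  ni <- vapply(data$subjects, function(b) length(b$times), integer(1L))
  if (all(ni == 1L)) {
    warning("likelihood is flat in tau (single observation per subject)")
    return(tau_init)
  }
  caches <- lapply(data$subjects, quadform_cache, omega = omega)
  p <- data$p
  # -2 * (tau-dependent part of the log-likelihood)
  neg2 <- function(log_tau) {
    tau <- exp(log_tau)
    tot <- 0
    for (ca in caches) {
      g <- quadform_grid(ca, tau)
      tot <- tot + p * g$logdet + g$quad
    }
    tot
  }
  lo <- max(log(TAU_MIN), log(tau_init) - span * log(10))
  hi <- min(log(TAU_MAX), log(tau_init) + span * log(10))
  opt <- stats::optimize(neg2, c(lo, hi), tol = 1e-6)
  tau_hat <- exp(opt$minimum)
  # never return a worse point than the incumbent
  if (tau_init >= TAU_MIN && tau_init <= TAU_MAX &&
      neg2(log(tau_init)) < opt$objective) tau_init else tau_hat
}

# ---- Monte-Carlo EM (heterogeneous / covariate-adjusted) -------------------

# log-spaced quadrature/sampling grid for the tau posterior, with
# trapezoid-style cell widths for inverse-CDF sampling at the grid atoms
TAU_GRID_SIZE <- 2048L
tau_grid_points <- function() {
  g <- exp(seq(log(TAU_MIN), log(TAU_MAX), length.out = TAU_GRID_SIZE))
  mid <- c(g[1], sqrt(g[-1] * g[-length(g)]), g[length(g)])
  list(tau = g, width = diff(mid), logwidth = log(diff(mid)))
}

#' Draw from the posterior of a subject's dampening rate
#'
#' Samples `h` values of `tau_i` from the normalized conditional density
#' (exponential prior times Gaussian likelihood) restricted to
#' `[1e-4, 1e4]`, by inverse-CDF sampling on a 2048-point log-spaced grid.
#' Weights are normalized in log space (log-sum-exp), so extreme densities
#' never underflow to all-zero.
#'
#' @inheritParams tau_posterior_logdensity
#' @param h number of draws.
#' @return numeric vector of `h` draws (values on the grid atoms).
#' @export
sample_tau_posterior <- function(block, omega, alpha_i, h) {
  stopifnot(h >= 1L)
  es <- estep_subject(block, omega, alpha_i, stats::runif(h))
  es$draws
}

# Full E-step for one subject: posterior draws plus the Monte-Carlo
# estimates of E[tau_i], E[S_i(tau_i)] and E[log|Phi_i|]. Draws are made
# by inverse CDF at the supplied uniforms `u`, so the EM loop can reuse
# one set of uniforms across iterations (common random numbers): the
# Monte-Carlo EM update then becomes a deterministic map and the stopping
# rule behaves as in exact EM.
estep_subject <- function(block, omega, alpha_i, u, grid = tau_grid_points()) {
  p <- ncol(block$values)
  cache <- quadform_cache(block, omega)
  g <- quadform_grid(cache, grid$tau, keep_bands = TRUE)
  lw <- -(p / 2) * g$logdet - g$quad / 2 - alpha_i * grid$tau + grid$logwidth
  w <- exp(lw - max(lw))
  cw <- cumsum(w) / sum(w)
  idx <- pmin(findInterval(u, cw) + 1L, TAU_GRID_SIZE)
  draws <- grid$tau[idx]
  S <- s_matrix_bands(colMeans(g$A[idx, , drop = FALSE]),
                      if (ncol(g$B)) colMeans(g$B[idx, , drop = FALSE]) else numeric(0),
                      block$values)
  list(draws = draws, tau_mean = mean(draws), S = S,
       logphi_mean = mean(g$logdet[idx]))
}

#' Closed-form prior-rate update of the heterogeneous model
#'
#' The M-step for the exponential prior rate: the reciprocal of the sample
#' mean of the posterior expectations of the subject-level rates.
#'
#' @param tau_post_means length-`m` vector of posterior means `E[tau_i]`.
#' @return updated scalar rate `alpha = m / sum(E[tau_i])`.
#' @export
update_alpha <- function(tau_post_means) {
  if (any(tau_post_means <= 0)) stop("posterior means must be positive")
  length(tau_post_means) / sum(tau_post_means)
}

#' Covariate-model M-step objective for the prior-rate coefficients
#'
#' The smooth convex function `sum_i(-a'x_i + exp(a'x_i) * E[tau_i])`
#' minimized over the coefficient vector in the covariate-adjusted M-step.
#'
#' @param alpha coefficient vector (intercept first).
#' @param X `m x (q+1)` design matrix with leading column of ones.
#' @param tau_means posterior means `E[tau_i]`.
#' @return scalar objective value.
#' @export
alpha_objective <- function(alpha, X, tau_means) {
  eta <- drop(X %*% alpha)
  sum(-eta + exp(eta) * tau_means)
}

alpha_gradient <- function(alpha, X, tau_means) {
  eta <- drop(X %*% alpha)
  drop(crossprod(X, exp(eta) * tau_means - 1))
}

# BFGS on internally standardized covariates, then Newton polish to
# gradient norm <= 1e-8 (the objective is strictly convex for full-rank X)
update_alpha_covariate <- function(X, tau_means, alpha_start) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  q <- ncol(X) - 1L
  mu <- if (q) colMeans(X[, -1L, drop = FALSE]) else numeric(0)
  sd_ <- if (q) apply(X[, -1L, drop = FALSE], 2L, stats::sd) else numeric(0)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Z <- X
  if (q) Z[, -1L] <- sweep(sweep(X[, -1L, drop = FALSE], 2L, mu), 2L, sd_, "/")
  # start on the standardized scale
  b0 <- alpha_start
  if (q) {
    b0[-1L] <- alpha_start[-1L] * sd_
    b0[1L] <- alpha_start[1L] + sum(alpha_start[-1L] * mu)
  }
  opt <- stats::optim(b0, fn = alpha_objective, gr = alpha_gradient,
                      X = Z, tau_means = tau_means, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500L))
  b <- opt$par
  for (k in seq_len(25L)) {
    gr <- alpha_gradient(b, Z, tau_means)
    if (sqrt(sum(gr^2)) <= 1e-8) break
    eta <- drop(Z %*% b)
    H <- crossprod(Z, Z * (exp(eta) * tau_means))
    b <- b - solve(H, gr)
  }
  a <- b
  if (q) {
    a[-1L] <- b[-1L] / sd_
    a[1L] <- b[1L] - sum(a[-1L] * mu)
  }
  a
}

# shared MCEM loop; X = NULL -> heterogeneous model (intercept-only prior
# with closed-form rate update), otherwise covariate-adjusted (BFGS M-step).
#
# The expensive E-step pieces (the quadratic-form grids) depend on Omega
# only; the prior rates merely re-weight the grid. Each outer iteration
# therefore solves the prior-rate fixed point to convergence by cheap
# re-weighted E/M cycles (each cycle is an exact EM step, so monotonicity
# of the observed-data objective is preserved), then updates Omega by one
# graphical-lasso step on the expected second-moment matrix. Stopping
# measures the change of the per-subject prior rates alpha_i on the rate
# scale, so the intercept-only covariate model follows the exact iteration
# schedule of the heterogeneous solver.
fit_mcem <- function(data, lambda, X = NULL, alpha_init = 10, h = 500L,
                     tol = 1e-3, max_outer = 30L, penalize_diag = FALSE,
                     gl_tol = 1e-4, warm = NULL) {
  gl_tol_em <- max(gl_tol, 1e-3)  # looser inner tolerance; final pass tight
  gl_iter_em <- 40L               # sweep cap inside EM iterations
  m <- data$m; p <- data$p; n <- data$n
  covariate <- !is.null(X)
  if (covariate) {
    X <- as.matrix(X)
    if (nrow(X) != m) stop("design matrix must have one row per subject")
    if (any(!is.finite(X))) stop("covariates must be finite")
  }
  if (h < 1L) stop("h must be at least 1")
  grid <- tau_grid_points()

  if (covariate) {
    coefs <- if (!is.null(warm$coefs)) warm$coefs else
      c(log(alpha_init), rep(0, ncol(X) - 1L))
    rates0 <- exp(drop(X %*% coefs))
  } else {
    alpha <- if (!is.null(warm$alpha)) warm$alpha else alpha_init
    rates0 <- rep(alpha, m)
  }
  gl_state <- warm$gl
  converged <- FALSE
  it <- 0L

  # one fixed uniform vector per subject, reused across EM iterations
  # (common random numbers); the refinement pass draws a fresh 10x set
  U <- lapply(seq_len(m), function(i) stats::runif(h))

  # Omega-dependent precompute: quadratic-form grids per subject
  precompute <- function(omega) {
    lapply(data$subjects, function(b) {
      g <- quadform_grid(quadform_cache(b, omega), grid$tau, keep_bands = TRUE)
      g$lw0 <- -(p / 2) * g$logdet - g$quad / 2 + grid$logwidth
      g
    })
  }

  draw_idx <- function(pre_i, alpha_i, u) {
    w <- exp(pre_i$lw0 - alpha_i * grid$tau -
               max(pre_i$lw0 - alpha_i * grid$tau))
    cw <- cumsum(w) / sum(w)
    pmin(findInterval(u, cw) + 1L, TAU_GRID_SIZE)
  }

  tau_means_at <- function(pre, rates, unif) {
    vapply(seq_len(m), function(i) {
      mean(grid$tau[draw_idx(pre[[i]], rates[i], unif[[i]])])
    }, numeric(1L))
  }

  # inner fixed-point solve of the prior rates for fixed Omega
  solve_rates <- function(pre, rates, unif) {
    for (k in seq_len(200L)) {
      tm <- tau_means_at(pre, rates, unif)
      if (covariate) {
        coefs <<- update_alpha_covariate(X, tm, coefs)
        new <- exp(drop(X %*% coefs))
      } else {
        alpha <<- update_alpha(tm)
        new <- rep(alpha, m)
      }
      done <- max(abs(new - rates)) < tol / 10
      rates <- new
      if (done) break
    }
    rates
  }

  # moment summaries at given rates (draws at the supplied uniforms)
  summarize <- function(pre, rates, unif) {
    tm <- numeric(m); lp <- numeric(m)
    S0 <- matrix(0, p, p)
    for (i in seq_len(m)) {
      g <- pre[[i]]
      idx <- draw_idx(g, rates[i], unif[[i]])
      tm[i] <- mean(grid$tau[idx])
      lp[i] <- mean(g$logdet[idx])
      S0 <- S0 + s_matrix_bands(
        colMeans(g$A[idx, , drop = FALSE]),
        if (ncol(g$B)) colMeans(g$B[idx, , drop = FALSE]) else numeric(0),
        data$subjects[[i]]$values)
    }
    list(tau_means = tm, S0 = (S0 + t(S0)) / (2 * n), logphi = lp)
  }

  # initial network from the second-moment matrix at the prior-mean rates
  if (is.null(gl_state) || is.null(warm$omega)) {
    gl <- glasso_fit(sbar(1 / rates0, data), lambda, penalize_diag, gl_tol_em,
                     max_iter = gl_iter_em, warm = gl_state)
    gl_state <- list(w = gl$w, b = gl$b)
    omega0 <- gl$omega
  } else {
    omega0 <- warm$omega
  }

  # log-scale parameter vector driving the rates (shared Aitken machinery
  # for the scalar heterogeneous rate and the covariate coefficients)
  theta_of <- function() if (covariate) coefs else log(alpha)
  set_theta <- function(th) {
    if (covariate) {
      coefs <<- th
      exp(drop(X %*% th))
    } else {
      alpha <<- exp(th)
      rep(alpha, m)
    }
  }

  es <- NULL
  th_prev2 <- th_prev1 <- NULL
  repeat {
    it <- it + 1L
    pre <- precompute(omega0)
    rates <- solve_rates(pre, rates0, U)
    th <- theta_of()
    # Aitken delta-squared acceleration of the (deterministic, common
    # random numbers) outer map, every third iteration, clamped
    if (!is.null(th_prev2) && it %% 3L == 0L) {
      d1 <- th_prev1 - th_prev2
      d2 <- th - th_prev1
      r <- ifelse(abs(d1) > 1e-12, d2 / d1, 0)
      r <- pmax(pmin(r, 0.995), -0.995)
      step <- pmax(pmin(d2 * r / (1 - r), 2), -2)
      th_acc <- th + step
      if (all(is.finite(th_acc))) {
        rates <- set_theta(th_acc)
        th <- th_acc
      }
      th_prev2 <- th_prev1 <- NULL
    } else {
      th_prev2 <- th_prev1
      th_prev1 <- th
    }
    es <- summarize(pre, rates, U)
    gl <- tryCatch(
      glasso_fit(es$S0, lambda, penalize_diag, gl_tol_em,
                 max_iter = gl_iter_em, warm = gl_state),
      error = function(e) NULL)
    if (is.null(gl)) {
      # M-step numerically infeasible (degenerate expected second-moment
      # matrix): keep the last valid iterate
      warning("M-step graphical lasso failed at iteration ", it,
              "; returning last valid iterate")
      rates0 <- rates
      break
    }
    gl_state <- list(w = gl$w, b = gl$b)
    omega <- gl$omega
    done <- max(abs(rates - rates0) / pmax(rates0, 1)) < tol &&
      max(abs(omega - omega0)) < tol
    rates0 <- rates; omega0 <- omega
    if (done) { converged <- TRUE; break }
    if (it >= max_outer) break
  }

  # refinement pass with 10x the Monte-Carlo budget for the reported
  # posterior means, surrogate likelihood and final parameter values
  U10 <- lapply(seq_len(m), function(i) stats::runif(10L * h))
  pre <- precompute(omega0)
  rates0 <- solve_rates(pre, rates0, U10)
  es <- summarize(pre, rates0, U10)
  gl <- tryCatch(
    glasso_fit(es$S0, lambda, penalize_diag, gl_tol, warm = gl_state),
    error = function(e) NULL)
  if (!is.null(gl)) {
    omega0 <- gl$omega
    gl_state <- list(w = gl$w, b = gl$b)
  }

  ld <- determinant(omega0, logarithm = TRUE)
  if (ld$sign <= 0) stop("fitted precision matrix lost positive definiteness")
  # EM surrogate for the (intractable) marginal log-likelihood: expected
  # complete-data log-likelihood at convergence, E[log|Phi_i|] estimated
  # from the refinement draws, plus the exponential-prior terms
  ll <- -0.5 * (p * sum(es$logphi) - n * as.numeric(ld$modulus) +
                  n * sum(es$S0 * omega0)) +
    sum(log(rates0) - rates0 * es$tau_means)

  out <- list(omega = omega0, lambda = lambda, sbar_hat = es$S0,
              tau_i = stats::setNames(es$tau_means,
                vapply(data$subjects, `[[`, character(1L), "subject_id")),
              loglik = ll, loglik_surrogate = TRUE,
              penalized_objective = -2 * ll + n * lambda *
                l1_norm(omega0, penalize_diag),
              iterations = it, converged = converged, h = h,
              gl_state = gl_state,
              penalize_diag = penalize_diag)
  if (covariate) {
    out$coefficients <- stats::setNames(coefs, colnames(X))
    out$alpha <- NULL
  } else {
    out$alpha <- alpha
  }
  out
}
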
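# Synthetic-data engine: sparse random precision matrices, irregular
# observation times, Kronecker-structured Gaussian draws, heterogeneous
# sub-communities, covariate-driven dampening rates, and left-censoring.

#' Preset dampening rates used throughout the simulation study
#'
#' Named from strongest temporal correlation (`s4`, tau = 0.018) to weakest
#' (`s1`, tau = 0.36).
#' @export
tau_presets <- c(s1 = 0.36, s2 = 0.14, s3 = 0.049, s4 = 0.018)

#' Generate a sparse ground-truth precision matrix
#'
#' Draws an Erdos-Renyi adjacency over the `choose(p, 2)` pairs with the
#' given edge density, then fills in a positive-definite precision matrix
#' with exactly that support:
#'
#' * `method = "gwishart"` (default): a draw from the G-Wishart
#'   distribution `W_G(b, I)` via a full Wishart draw followed by
#'   Lenkoski-style iterative graphical completion — the standard
#'   random-network generator in the Bayesian graphical-model literature
#'   (shape `b = 3`, identity scale), giving realistically strong partial
#'   correlations.
#' * `method = "dominance"`: off-diagonal weights uniform in
#'   `+/- [0.3, 0.7]` (random sign), diagonal set by diagonal dominance
#'   (`|row sum| + 0.5`), then rescaled so the implied covariance is a
#'   correlation matrix; gives uniformly weak partial correlations.
#'
#' @param p number of taxa (nodes).
#' @param edge_density expected fraction of present edges.
#' @param method weight scheme (see above).
#' @param b G-Wishart shape parameter (>= 3).
#' @param weight_range absolute-weight range for present edges
#'   (`"dominance"` only).
#' @param diag_add diagonal-dominance margin (`"dominance"` only).
#' @param max_tries regeneration attempts if positive definiteness fails.
#' @return object of class `"sggm_truth"`: list with `adjacency` (binary,
#'   zero diagonal), `omega` (positive-definite precision matrix), `sigma`
#'   (its inverse), `p`.
#' @export
generate_precision <- function(p, edge_density,
                               method = c("gwishart", "dominance"),
                               b = 3, weight_range = c(0.3, 0.7),
                               diag_add = 0.5, max_tries = 20L) {
  stopifnot(p >= 2L, edge_density > 0, edge_density < 1)
  method <- match.arg(method)
  for (try in seq_len(max_tries)) {
    A <- matrix(0L, p, p)
    up <- upper.tri(A)
    A[up] <- stats::rbinom(sum(up), 1L, edge_density)
    A <- A + t(A)
    O <- if (method == "gwishart") rgwishart(A, b = b)
         else dominance_precision(A, weight_range, diag_add)
    if (is.null(O)) next
    Sg <- solve(O)
    if (method == "dominance") {
      d <- sqrt(diag(Sg))
      Sg <- Sg / tcrossprod(d)           # correlation form
      O <- O * tcrossprod(d)             # matching precision rescale
    }
    O <- 0.5 * (O + t(O))
    Sg <- 0.5 * (Sg + t(Sg))
    return(structure(list(adjacency = A, omega = O, sigma = Sg, p = p),
                     class = "sggm_truth"))
  }
  stop("failed to generate a positive-definite precision matrix")
}

dominance_precision <- function(A, weight_range, diag_add) {
  p <- nrow(A)
  up <- upper.tri(A)
  O <- matrix(0, p, p)
  ne <- sum(A[up])
  w <- stats::runif(ne, weight_range[1L], weight_range[2L]) *
    sample(c(-1, 1), ne, replace = TRUE)
  O[up][A[up] == 1L] <- w
  O <- O + t(O)
  diag(O) <- rowSums(abs(O)) + diag_add
  ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(NULL)
  O
}

# G-Wishart draw W_G(b, I): sample K ~ Wishart(b + p - 1, I), set
# Sigma* = K^-1, then iterate the graphical completion of Lenkoski (2013):
# for each node, replace the covariances to non-neighbours so that the
# inverse has zeros exactly off the graph's support.
rgwishart <- function(A, b = 3, tol = 1e-8, max_sweeps = 200L) {
  p <- nrow(A)
  K <- drop(stats::rWishart(1L, df = b + p - 1, Sigma = diag(p))[, , 1L])
  Sstar <- solve(K)
  W <- Sstar
  nb <- lapply(seq_len(p), function(j) which(A[, j] == 1L))
  for (s in seq_len(max_sweeps)) {
    W_old <- W
    for (j in seq_len(p)) {
      N <- nb[[j]]
      wj <- if (length(N)) {
        beta <- solve(W[N, N, drop = FALSE], Sstar[N, j])
        drop(W[, N, drop = FALSE] %*% beta)
      } else {
        rep(0, p)
      }
      W[-j, j] <- wj[-j]
      W[j, -j] <- wj[-j]
    }
    if (max(abs(W - W_old)) < tol) break
  }
  O <- solve(W)
  O[A == 0L & row(O) != col(O)] <- 0   # exact zeros off the support
  O <- 0.5 * (O + t(O))
  ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(NULL)
  O
}

#' Generate irregular per-subject observation times
#'
#' `n_i ~ Poisson(mean_ni)` truncated to at least 2 (so every subject
#' informs the dampening rate); consecutive gaps are
#' `max(Poisson(gap_mean), min_gap)`; times start at 0.
#'
#' @param m number of subjects.
#' @param mean_ni Poisson mean of the number of observations.
#' @param gap_mean Poisson mean of the raw gaps.
#' @param min_gap floor applied to every gap.
#' @return list of strictly increasing time vectors.
#' @export
generate_times <- function(m, mean_ni, gap_mean = 1, min_gap = 0.5) {
  stopifnot(m >= 1L, mean_ni > 0)
  lapply(seq_len(m), function(i) {
    ni <- 0L
    while (ni < 2L) ni <- stats::rpois(1L, mean_ni)
    cumsum(c(0, pmax(stats::rpois(ni - 1L, gap_mean), min_gap)))
  })
}

# one subject's ni x p matrix-normal draw: rows ~ N(0, Sigma), row
# correlation Phi (stacked covariance Phi kron Sigma)
rmatnorm_kron <- function(times, tau, chol_sigma_upper) {
  ni <- length(times)
  p <- ncol(chol_sigma_upper)
  Z <- matrix(stats::rnorm(ni * p), ni, p)
  Lphi <- t(chol(build_phi(tau, times)))
  Lphi %*% Z %*% chol_sigma_upper
}

#' Simulate a longitudinal dataset from the generative model
#'
#' Draws per-subject observations `y_i ~ N(0, Phi_i kron Sigma)` via
#' Cholesky factors of the Kronecker components, under one of four
#' dampening scenarios:
#'
#' * `"homogeneous"`: shared rate `tau`.
#' * `"heterogeneous"`: `tau_i ~ Exp(alpha)` (give `alpha` or `Etau`).
#' * `"covariate"`: `tau_i ~ Exp(exp(coefs' x_i))` with
#'   `x_1 ~ N(0,1)`, `x_2 ~ Bernoulli(0.5)` (default design), or a
#'   user-supplied design `X` (no intercept column).
#' * `"two_community"`: the taxa split into two independent blocks (first
#'   half community A) with their own rates `tau` and `tau_B` (or rates
#'   drawn from `Exp(alpha)`, `Exp(alpha_B)`); the truth precision is
#'   block-diagonal accordingly.
#'
#' @param p,m,mean_ni,edge_density dimensions of the study: taxa, subjects,
#'   mean observations per subject, expected edge density of the truth.
#' @param scenario dampening scenario (see above).
#' @param tau,alpha,Etau,coefs,X,tau_B,alpha_B scenario parameters.
#' @param truth optional pre-generated `"sggm_truth"` (ignored for
#'   `"two_community"`, which builds a block-diagonal truth).
#' @param censor optional `c(q1, q2)`: apply [censor_left] to the data.
#' @param seed optional integer seed.
#' @return list with `data` (a [longitudinal_data], already centered),
#'   `truth` (`"sggm_truth"`, augmented with the scenario parameters,
#'   per-subject `tau_i`, and covariates where applicable).
#' @export
simulate_sggm <- function(p = 80L, m = 10L, mean_ni = 10,
                          edge_density = 0.1,
                          scenario = c("homogeneous", "heterogeneous",
                                       "covariate", "two_community"),
                          tau = 0.018, alpha = NULL, Etau = NULL,
                          coefs = c(4, 0, 0), X = NULL,
                          tau_B = NULL, alpha_B = NULL,
                          truth = NULL, censor = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)

  if (scenario == "two_community") {
    pa <- floor(p / 2); pb <- p - pa
    ta <- generate_precision(pa, edge_density)
    tb <- generate_precision(pb, edge_density)
    truth <- structure(list(
      adjacency = as.matrix(Matrix_bdiag(ta$adjacency, tb$adjacency)),
      omega = as.matrix(Matrix_bdiag(ta$omega, tb$omega)),
      sigma = as.matrix(Matrix_bdiag(ta$sigma, tb$sigma)), p = p),
      class = "sggm_truth")
    truth$community <- rep(c("A", "B"), c(pa, pb))
  } else if (is.null(truth)) {
    truth <- generate_precision(p, edge_density)
  } else {
    p <- truth$p
  }

  times <- generate_times(m, mean_ni)

  if (scenario == "heterogeneous") {
    if (is.null(alpha)) {
      if (is.null(Etau)) stop("give alpha or Etau for the heterogeneous scenario")
      alpha <- 1 / Etau
    }
    tau_i <- stats::rexp(m, rate = alpha)
    truth$alpha <- alpha
  } else if (scenario == "covariate") {
    if (is.null(X)) {
      X <- cbind(x1 = stats::rnorm(m), x2 = stats::rbinom(m, 1L, 0.5))
    }
    X <- as.matrix(X)
    if (length(coefs) != ncol(X) + 1L) {
      stop("coefs must have length ncol(X) + 1 (intercept first)")
    }
    rates <- exp(drop(cbind(1, X) %*% coefs))
    tau_i <- stats::rexp(m, rate = rates)
    truth$coefs <- coefs
    truth$X <- X
  } else if (scenario == "two_community") {
    if (!is.null(alpha) || !is.null(alpha_B)) {
      if (is.null(alpha) || is.null(alpha_B)) {
        stop("give both alpha and alpha_B for random two-community rates")
      }
      tau_i <- stats::rexp(m, alpha)
      tau_i_B <- stats::rexp(m, alpha_B)
    } else {
      if (is.null(tau_B)) stop("give tau_B for the two-community scenario")
      tau_i <- rep(tau, m)
      tau_i_B <- rep(tau_B, m)
    }
    truth$tau_A <- tau; truth$tau_B <- tau_B
  } else {
    tau_i <- rep(tau, m)
    truth$tau <- tau
  }
  truth$tau_i <- tau_i

  taxa <- sprintf("taxon%02d", seq_len(p))
  if (scenario == "two_community") {
    pa <- sum(truth$community == "A")
    Ua <- chol(truth$sigma[seq_len(pa), seq_len(pa)])
    Ub <- chol(truth$sigma[-seq_len(pa), -seq_len(pa)])
    truth$tau_i_B <- tau_i_B
    blocks <- lapply(seq_len(m), function(i) {
      Y <- cbind(rmatnorm_kron(times[[i]], tau_i[i], Ua),
                 rmatnorm_kron(times[[i]], tau_i_B[i], Ub))
      list(subject_id = as.character(i), times = times[[i]], values = Y)
    })
  } else {
    U <- chol(truth$sigma)
    blocks <- lapply(seq_len(m), function(i) {
      list(subject_id = as.character(i), times = times[[i]],
           values = rmatnorm_kron(times[[i]], tau_i[i], U))
    })
  }
  if (scenario == "covariate") {
    for (i in seq_len(m)) {
      blocks[[i]]$covariates <- stats::setNames(X[i, ], colnames(X))
    }
  }
  data <- new_longitudinal_data(blocks, taxon_names = taxa, center = FALSE)

  if (!is.null(censor)) {
    data <- censor_left(data, censor[1L], censor[2L])
    truth$censoring <- c(q1 = censor[1L], q2 = censor[2L])
  }
  # center after any censoring, as a loader would
  data <- recenter(data)
  list(data = data, truth = truth)
}

Matrix_bdiag <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  out[-seq_len(nrow(A)), -seq_len(ncol(A))] <- B
  out
}

recenter <- function(data) {
  blocks <- data$subjects
  new_longitudinal_data(blocks, data$taxon_names, center = TRUE)
}

#' Left-censor a dataset
#'
#' Emulates zero inflation of sequencing data on the transformed scale:
#' per taxon, the empirical `q1`-quantile over all rows pooled is the
#' detection limit; every value below it is independently replaced by the
#' limit with probability `q2`.
#'
#' @param data a [longitudinal_data] object.
#' @param q1 quantile level in (0, 1).
#' @param q2 replacement probability in \[0, 1\].
#' @return the censored dataset (not re-centered).
#' @export
censor_left <- function(data, q1, q2) {
  stopifnot(inherits(data, "longitudinal_data"),
            q1 > 0, q1 < 1, q2 >= 0, q2 <= 1)
  allv <- do.call(rbind, lapply(data$subjects, `[[`, "values"))
  qs <- apply(allv, 2L, stats::quantile, probs = q1, names = FALSE)
  data$subjects <- lapply(data$subjects, function(b) {
    V <- b$values
    for (j in seq_len(ncol(V))) {
      low <- which(V[, j] < qs[j])
      if (length(low)) {
        hit <- low[stats::runif(length(low)) < q2]
        V[hit, j] <- qs[j]
      }
    }
    b$values <- V
    b
  })
  data
}
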
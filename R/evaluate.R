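# Network-recovery evaluation: TPR/FPR against a known truth, connection
# probabilities across solution paths, ROC/AUC, and the independent-data
# baselines (plain graphical lasso, neighborhood selection).

#' Binary adjacency of a fitted network
#'
#' @param x an `"sggm"` fit, an `"sggm_truth"`, or a numeric matrix.
#' @param threshold absolute-value threshold defining an edge.
#' @return symmetric binary matrix with zero diagonal.
#' @export
adjacency <- function(x, threshold = 1e-8) {
  M <- if (inherits(x, "sggm")) x$omega
       else if (inherits(x, "sggm_truth")) return(x$adjacency)
       else as.matrix(x)
  A <- (abs(M) > threshold) * 1L
  diag(A) <- 0L
  A
}

#' True- and false-positive edge rates
#'
#' `TPR = TP / P` over the true edges and `FPR = FP / N` over the true
#' non-edges, undirected pairs counted once; diagonals ignored.
#'
#' @param est,truth adjacency matrices (or objects accepted by
#'   [adjacency]).
#' @return named vector `c(tpr, fpr)`.
#' @export
tpr_fpr <- function(est, truth) {
  E <- adjacency(est); A <- adjacency(truth)
  if (!identical(dim(E), dim(A))) stop("dimension mismatch")
  up <- upper.tri(A)
  e <- E[up]; a <- A[up]
  P <- sum(a == 1L); N <- sum(a == 0L)
  if (P == 0L) stop("truth has no edges: TPR undefined")
  c(tpr = sum(e == 1L & a == 1L) / P,
    fpr = if (N == 0L) NA_real_ else sum(e == 1L & a == 0L) / N)
}

#' Connection probabilities across replicated solution paths
#'
#' For each replicate, the within-path proportion of networks containing
#' each edge is computed first; these proportions are then averaged across
#' replicates. The resulting scores in \[0, 1\] are the basis of the ROC
#' analysis.
#'
#' @param paths a list of replicates; each replicate is an `"sggm_path"`
#'   or a list of adjacency matrices.
#' @param threshold edge threshold for fitted precision matrices.
#' @return symmetric matrix of edge scores in \[0, 1\].
#' @export
connection_probabilities <- function(paths, threshold = 1e-8) {
  stopifnot(length(paths) >= 1L)
  per_rep <- lapply(paths, function(pp) {
    adjs <- if (inherits(pp, "sggm_path")) {
      lapply(pp$fits, adjacency, threshold = threshold)
    } else {
      lapply(pp, adjacency, threshold = threshold)
    }
    Reduce(`+`, adjs) / length(adjs)
  })
  Reduce(`+`, per_rep) / length(per_rep)
}

#' ROC curve and AUC from edge scores
#'
#' Sweeps a threshold over the distinct score values, computing (FPR, TPR)
#' at each, and integrates by the trapezoid rule. Equivalent to the
#' Mann-Whitney statistic `U / (P * N)` on the pairwise scores.
#'
#' @param scores symmetric matrix of edge scores (e.g. connection
#'   probabilities).
#' @param truth true adjacency (or object accepted by [adjacency]).
#' @return list with `points` (data.frame of fpr/tpr/threshold) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  A <- adjacency(truth)
  up <- upper.tri(A)
  s <- as.matrix(scores)[up]
  a <- A[up]
  P <- sum(a == 1L); N <- sum(a == 0L)
  if (P == 0L || N == 0L) stop("need both edges and non-edges in the truth")
  th <- sort(unique(s), decreasing = TRUE)
  pts <- t(vapply(th, function(t0) {
    pos <- s >= t0
    c(fpr = sum(pos & a == 0L) / N, tpr = sum(pos & a == 1L) / P)
  }, numeric(2L)))
  pts <- rbind(c(0, 0), pts)
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
  auc <- sum(diff(pts[, "fpr"]) *
               (utils::head(pts[, "tpr"], -1) + utils::tail(pts[, "tpr"], -1)) / 2)
  list(points = data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"]), auc = auc)
}

# pooled empirical second-moment matrix (rows already centered globally)
pooled_covariance <- function(data) {
  allv <- do.call(rbind, lapply(data$subjects, `[[`, "values"))
  crossprod(allv) / nrow(allv)
}

#' Plain graphical-lasso baseline path
#'
#' Ignores the longitudinal correlation: pools all rows, computes the
#' empirical second-moment matrix, and runs the graphical lasso over the
#' penalty grid. Log-likelihoods are the independent-data Gaussian values,
#' so EBIC selection applies as usual.
#'
#' @inheritParams sggm_path
#' @param standardize operate on the correlation (unit-variance) scale,
#'   as the SPIEC-EASI-style pipelines do.
#' @return an `"sggm_path"` object (each fit of class `"sggm"` with
#'   `model = "glasso_pooled"`).
#' @export
baseline_glasso <- function(data, lambdas = NULL, nlambda = 15L,
                            lambda_min_ratio = 0.05, penalize_diag = FALSE,
                            standardize = TRUE, edge_threshold = 1e-8,
                            ebic_T = 2) {
  stopifnot(inherits(data, "longitudinal_data"))
  S <- pooled_covariance(data)
  if (standardize) S <- stats::cov2cor(S)
  if (is.null(lambdas)) {
    lambdas <- default_lambda_grid(S, nlambda, lambda_min_ratio)
  }
  n <- data$n
  warm <- NULL
  fits <- lapply(lambdas, function(l) {
    gl <- glasso_fit(S, l, penalize_diag, warm = warm)
    warm <<- list(w = gl$w, b = gl$b)
    ld <- as.numeric(determinant(gl$omega, logarithm = TRUE)$modulus)
    f <- list(omega = gl$omega, lambda = l,
              loglik = (n / 2) * (ld - sum(S * gl$omega)),
              n_edges = count_edges(gl$omega, edge_threshold),
              model = "glasso_pooled", edge_threshold = edge_threshold,
              n = n, p = data$p, m = data$m, converged = gl$converged,
              taxon_names = data$taxon_names)
    class(f) <- "sggm"
    f
  })
  out <- structure(list(fits = fits, lambda = lambdas,
                        n_edges = vapply(fits, `[[`, numeric(1L), "n_edges"),
                        loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
                        model = "glasso_pooled", n = n, p = data$p,
                        ebic_T = ebic_T),
                   class = "sggm_path")
  out$ebic <- vapply(fits, ebic, numeric(1L), T = ebic_T)
  out$selected <- which.min(out$ebic)
  out
}

#' Neighborhood-selection baseline path
#'
#' Meinshausen-Buhlmann style: a lasso regression of each node on all
#' others (pooled rows, longitudinal correlation ignored) over a shared
#' penalty grid; an edge is kept where the coefficient is nonzero in both
#' directions (`rule = "AND"`, default) or either direction
#' (`rule = "OR"`). For model selection a Gaussian pseudo-likelihood EBIC
#' is used: `sum_j n*log(RSS_j/n)` plus the usual edge-count terms.
#'
#' @inheritParams sggm_path
#' @param rule symmetrization rule.
#' @param standardize scale columns to unit variance first.
#' @return list of class `"nh_path"` with `adjacencies` (one binary matrix
#'   per penalty), `lambda`, `n_edges`, `pseudo_ebic`, `selected`.
#' @export
baseline_neighborhood <- function(data, lambdas = NULL, nlambda = 15L,
                                  lambda_min_ratio = 0.05,
                                  rule = c("AND", "OR"), standardize = TRUE,
                                  ebic_T = 2) {
  rule <- match.arg(rule)
  stopifnot(inherits(data, "longitudinal_data"))
  allv <- do.call(rbind, lapply(data$subjects, `[[`, "values"))
  n <- nrow(allv); p <- ncol(allv)
  if (standardize) {
    sds <- apply(allv, 2L, stats::sd)
    sds[sds == 0] <- 1
    allv <- sweep(allv, 2L, sds, "/")
  }
  if (is.null(lambdas)) {
    # lambda_max on the glmnet scale: max_j,k |x_k' y_j| / n
    S <- crossprod(allv) / n
    diag(S) <- 0
    lmax <- max(abs(S))
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  }
  nl <- length(lambdas)
  nonzero <- array(FALSE, c(p, p, nl))
  rss <- matrix(0, p, nl)
  for (j in seq_len(p)) {
    fitj <- glmnet::glmnet(allv[, -j, drop = FALSE], allv[, j],
                           lambda = lambdas, standardize = FALSE,
                           intercept = FALSE)
    cf <- as.matrix(fitj$beta)  # (p-1) x nl (glmnet keeps the given order)
    resid <- allv[, j] - allv[, -j, drop = FALSE] %*% cf
    rss[j, ] <- colSums(resid^2)
    nonzero[j, -j, ] <- cf != 0
  }
  adjs <- vector("list", nl)
  n_edges <- numeric(nl)
  pseudo <- numeric(nl)
  for (k in seq_len(nl)) {
    A <- if (rule == "AND") (nonzero[, , k] & t(nonzero[, , k])) * 1L
         else (nonzero[, , k] | t(nonzero[, , k])) * 1L
    diag(A) <- 0L
    adjs[[k]] <- A
    n_edges[k] <- sum(A[upper.tri(A)])
    pseudo[k] <- sum(n * log(rss[, k] / n)) +
      n_edges[k] * log(n) + n_edges[k] * log(p) / ebic_T
  }
  structure(list(adjacencies = adjs, lambda = lambdas, n_edges = n_edges,
                 pseudo_ebic = pseudo, selected = which.min(pseudo),
                 rule = rule, n = n, p = p),
            class = "nh_path")
}

#' @export
print.nh_path <- function(x, ...) {
  cat("Neighborhood-selection path (", x$rule, " rule), ",
      length(x$lambda), " penalties; selected ", x$n_edges[x$selected],
      " edges\n", sep = "")
  invisible(x)
}
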
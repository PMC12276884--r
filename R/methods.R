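# S3 methods for fitted models.

#' @export
print.sggm <- function(x, ...) {
  cat("Stationary Gaussian graphical model fit (", x$model, ")\n", sep = "")
  cat(sprintf("  %d taxa, %d subjects, %d observations; lambda = %.4g\n",
              x$p, x$m, x$n, x$lambda))
  cat(sprintf("  edges: %d of %d pairs\n", x$n_edges, choose(x$p, 2)))
  if (!is.null(x[["tau"]])) {
    cat(sprintf("  dampening rate tau = %.4g\n", x[["tau"]]))
  }
  if (!is.null(x[["alpha"]])) {
    cat(sprintf("  prior rate alpha = %.4g (E tau = %.4g)\n",
                x[["alpha"]], 1 / x[["alpha"]]))
  }
  if (!is.null(x$coefficients)) {
    cat("  prior-rate coefficients (log scale):\n")
    print(round(x$coefficients, 4))
  }
  cat(sprintf("  log-likelihood%s = %.3f; %s after %d iteration(s)\n",
              if (isTRUE(x$loglik_surrogate)) " (EM surrogate)" else "",
              x$loglik,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
summary.sggm <- function(object, ebic_T = 2, ...) {
  A <- adjacency(object, object$edge_threshold)
  deg <- rowSums(A)
  structure(list(fit = object, ebic = ebic(object, T = ebic_T),
                 degree = stats::setNames(deg, object$taxon_names)),
            class = "summary.sggm")
}

#' @export
print.summary.sggm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  EBIC = %.3f\n", x$ebic))
  deg <- sort(x$degree, decreasing = TRUE)
  top <- utils::head(deg[deg > 0], 5L)
  if (length(top)) {
    cat("  highest-degree taxa:",
        paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the fitted precision matrix
#' @param object an `"sggm"` fit.
#' @param ... unused.
#' @export
coef.sggm <- function(object, ...) object$omega

#' @export
logLik.sggm <- function(object, ...) {
  structure(object$loglik, df = object$n_edges + object$p,
            nobs = object$n, class = "logLik")
}

#' Plot the estimated interaction network
#'
#' Draws the network graph (isolated taxa omitted by default); edge width
#' scales with partial-correlation magnitude, color with sign.
#'
#' @param x an `"sggm"` fit.
#' @param drop_isolated omit unconnected taxa.
#' @param ... passed to [igraph::plot.igraph].
#' @export
plot.sggm <- function(x, drop_isolated = TRUE, ...) {
  A <- adjacency(x, x$edge_threshold)
  # partial correlations: -omega_jk / sqrt(omega_jj * omega_kk)
  d <- sqrt(diag(x$omega))
  PC <- -x$omega / tcrossprod(d)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    w <- PC[el]
    igraph::E(g)$width <- 0.5 + 3 * abs(w) / max(abs(w))
    igraph::E(g)$color <- ifelse(w > 0, "steelblue", "firebrick")
  }
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  igraph::plot.igraph(g, vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(g)
}

#' @export
plot.sggm_path <- function(x, ...) {
  graphics::plot(log(x$lambda), x$ebic, type = "b", pch = 16,
                 xlab = "log(lambda)", ylab = "EBIC", ...)
  graphics::abline(v = log(x$lambda[x$selected]), lty = 2)
  invisible(x)
}

#' Simulate new data from a fitted model
#'
#' Draws datasets from the fitted precision matrix and dampening model at
#' the observation times of the original data (homogeneous fits use the
#' estimated shared rate; latent-rate fits draw subject rates from the
#' fitted exponential prior).
#'
#' @param object an `"sggm"` fit.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param data the [longitudinal_data] the model was fitted to (supplies
#'   observation times).
#' @param ... unused.
#' @return list of [longitudinal_data] objects.
#' @export
simulate.sggm <- function(object, nsim = 1, seed = NULL, data, ...) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(data, "longitudinal_data"))
  sigma <- solve(object$omega)
  sigma <- 0.5 * (sigma + t(sigma))
  U <- chol(sigma)
  lapply(seq_len(nsim), function(s) {
    blocks <- lapply(data$subjects, function(b) {
      tau_i <- if (!is.null(object[["tau"]])) object[["tau"]]
               else if (!is.null(object[["alpha"]])) stats::rexp(1L, object[["alpha"]])
               else stats::rexp(1L, exp(object$coefficients[1L]))
      b$values <- rmatnorm_kron(b$times, tau_i, U)
      b
    })
    new_longitudinal_data(blocks, data$taxon_names, center = FALSE)
  })
}
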
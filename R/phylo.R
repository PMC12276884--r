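# Network-phylogeny concordance: ALR preprocessing for compositional
# counts, shortest-path distance vectors on the estimated network and on
# the phylogenetic tree, and a taxon-label permutation test.

#' Additive log-ratio transform of longitudinal count data
#'
#' Preprocessing for compositional sequencing counts: taxa observed
#' (nonzero) in fewer than `rare_threshold` of the rows are summed into a
#' composite reference taxon; remaining zeros are replaced per taxon by its
#' minimum positive value divided by `zero_divisor`; each taxon is then
#' log-ratio transformed against the composite, and the composite itself is
#' excluded from the network taxa.
#'
#' @param x data.frame with subject-id and time columns plus nonnegative
#'   count columns (one per taxon).
#' @param subject,time column names.
#' @param rare_threshold minimum proportion of nonzero observations for a
#'   taxon to be kept individually.
#' @param zero_divisor divisor applied to the per-taxon minimum positive
#'   count when replacing zeros.
#' @param center passed to the dataset constructor (per-taxon centering).
#' @return a [longitudinal_data] of log-ratios (composite excluded).
#' @export
alr_transform <- function(x, subject = "subject_id", time = "time",
                          rare_threshold = 0.10, zero_divisor = 10,
                          center = TRUE) {
  x <- as.data.frame(x)
  taxa <- setdiff(names(x), c(subject, time))
  counts <- as.matrix(x[, taxa, drop = FALSE])
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  allzero <- colSums(counts > 0) == 0
  if (any(allzero)) {
    stop("taxa with no nonzero observations: ",
         paste(taxa[allzero], collapse = ", "))
  }
  prop_nonzero <- colMeans(counts > 0)
  rare <- prop_nonzero < rare_threshold
  if (!any(rare)) {
    stop("no taxon falls below the rare threshold to form the composite ",
         "reference; supply a pseudo-reference column instead")
  }
  composite <- rowSums(counts[, rare, drop = FALSE])
  kept <- counts[, !rare, drop = FALSE]
  # zero replacement: per-taxon minimum positive value / zero_divisor
  repl <- function(v) {
    z <- v == 0
    if (any(z)) v[z] <- min(v[!z]) / zero_divisor
    v
  }
  kept <- apply(kept, 2L, repl)
  composite <- repl(composite)
  lr <- log(kept / composite)
  out <- data.frame(x[[subject]], x[[time]], lr, check.names = FALSE)
  names(out)[1:2] <- c(subject, time)
  longitudinal_data(out, subject = subject, time = time, center = center)
}

# all-pairs hop-count (or branch-length) distances between tree tips,
# traversing internal nodes
tree_tip_distances <- function(tree, weighted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2L, as.character),
                                   directed = FALSE)
  w <- if (weighted) tree$edge.length else NULL
  tips <- as.character(seq_along(tree$tip.label))
  D <- igraph::distances(g, v = tips, to = tips, weights = w)
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

network_node_distances <- function(adj, names = NULL) {
  A <- adjacency(adj)
  if (!is.null(names)) dimnames(A) <- list(names, names)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::distances(g)
}

#' Paired shortest-path distance vectors for network and tree
#'
#' For every pair of taxa present in both the network and the tree, the
#' unweighted shortest-path hop count in the network (`d1`) and in the
#' tree graph (`d2`, internal nodes traversed; optionally branch-length
#' weighted). Pairs with no connecting path in the network are excluded
#' from both vectors.
#'
#' @param network adjacency matrix with taxon names as dimnames, or an
#'   `"sggm"` fit.
#' @param tree an [ape::phylo] tree whose tip labels are taxon names.
#' @param weighted use branch lengths for the tree distance instead of hop
#'   counts.
#' @return list with `pairs` (two-column character matrix), `d1`, `d2`.
#' @export
distance_vectors <- function(network, tree, weighted = FALSE) {
  nm <- if (inherits(network, "sggm")) network$taxon_names
        else rownames(as.matrix(network))
  if (is.null(nm)) stop("network needs taxon names")
  common <- intersect(nm, tree$tip.label)
  if (length(common) < 3L) stop("fewer than 3 taxa shared by network and tree")
  D1 <- network_node_distances(network, nm)[common, common]
  D2 <- tree_tip_distances(tree, weighted)[common, common]
  up <- which(upper.tri(D1), arr.ind = TRUE)
  keep <- is.finite(D1[up])
  up <- up[keep, , drop = FALSE]
  list(pairs = cbind(common[up[, 1L]], common[up[, 2L]]),
       d1 = D1[up], d2 = D2[up])
}

#' Permutation test for network-phylogeny concordance
#'
#' Tests whether taxa nearby on the phylogenetic tree are also nearby in
#' the estimated interaction network. The observed statistic `r0` is the
#' correlation between the paired shortest-path distance vectors; the null
#' distribution is built by relabelling the network's nodes with uniform
#' random permutations of the taxa (network structure fixed), rebuilding
#' `d1` and recomputing the correlation against the fixed tree distances.
#' One-sided p-value with the add-one convention:
#' `p = (1 + #\{r_i >= r0\}) / (1 + n_perm)`.
#'
#' @inheritParams distance_vectors
#' @param n_perm number of permutations.
#' @param method correlation type (`"pearson"` default, or `"spearman"`).
#' @return object of class `"sggm_permtest"`: list with `r0`, `p_value`,
#'   `null` (the permuted correlations), `n_perm`, `n_pairs`.
#' @export
permutation_test <- function(network, tree, n_perm = 5000L,
                             method = c("pearson", "spearman"),
                             weighted = FALSE) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1L)
  nm <- if (inherits(network, "sggm")) network$taxon_names
        else rownames(as.matrix(network))
  if (is.null(nm)) stop("network needs taxon names")
  common <- intersect(nm, tree$tip.label)
  if (length(common) < 3L) stop("fewer than 3 taxa shared by network and tree")
  D1 <- network_node_distances(network, nm)[common, common]
  D2 <- tree_tip_distances(tree, weighted)[common, common]
  K <- length(common)
  up <- upper.tri(D1)

  cor_of <- function(d1v, d2v) {
    keep <- is.finite(d1v)
    if (sum(keep) < 3L) return(NA_real_)
    d1k <- d1v[keep]; d2k <- d2v[keep]
    if (stats::sd(d1k) == 0 || stats::sd(d2k) == 0) return(NA_real_)
    stats::cor(d1k, d2k, method = method)
  }
  d2v <- D2[up]
  r0 <- cor_of(D1[up], d2v)
  if (is.na(r0)) stop("observed correlation undefined (degenerate distances)")
  null <- vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(K)
    cor_of(D1[pm, pm][up], d2v)
  }, numeric(1L))
  pv <- (1 + sum(null >= r0, na.rm = TRUE)) / (1 + n_perm)
  structure(list(r0 = r0, p_value = pv, null = null, n_perm = n_perm,
                 n_pairs = sum(is.finite(D1[up])), method = method),
            class = "sggm_permtest")
}

#' @export
print.sggm_permtest <- function(x, ...) {
  cat("Network-phylogeny concordance permutation test\n")
  cat(sprintf("  r0 = %.4f over %d taxon pairs (%s correlation)\n",
              x$r0, x$n_pairs, x$method))
  cat(sprintf("  one-sided p = %.4g (%d permutations)\n", x$p_value, x$n_perm))
  invisible(x)
}
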
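# ALR preprocessing, distance vectors, permutation test.

test_that("alr_transform applies composite, zero-replacement and log-ratio", {
  df <- data.frame(subject_id = rep(1, 4), time = 1:4,
                   A = c(10, 20, 5, 40), B = c(5, 0, 10, 20),
                   rare = c(0, 0, 2, 0))  # nonzero in 1/4 rows < 0.3
  d <- alr_transform(df, rare_threshold = 0.3, zero_divisor = 10,
                     center = FALSE)
  expect_equal(d$taxon_names, c("A", "B"))
  comp <- c(0.2, 0.2, 2, 0.2)           # composite: zeros -> min(2)/10
  B <- c(5, 0.5, 10, 20)                # zero -> min positive 5 / 10
  expect_equal(d$subjects[[1]]$values[, "A"], log(df$A / comp))
  expect_equal(d$subjects[[1]]$values[, "B"], log(B / comp))

  noz <- df; noz$rare <- c(1, 0, 0, 0)
  d2 <- alr_transform(noz, rare_threshold = 0.3, center = FALSE)
  expect_equal(ncol(d2$subjects[[1]]$values), 2)

  allrare <- df; allrare$rare <- NULL
  expect_error(alr_transform(allrare, rare_threshold = 0.1),
               "rare threshold")
  zero <- df; zero$A <- 0
  expect_error(alr_transform(zero, rare_threshold = 0.3), "A")
})

test_that("distance vectors use hop counts and drop disconnected pairs", {
  # star network: hub t1, leaves t2..t5 -> leaf-leaf distance 2
  p <- 5
  A <- matrix(0L, p, p)
  A[1, 2:5] <- 1L; A[2:5, 1] <- 1L
  dimnames(A) <- list(paste0("t", 1:5), paste0("t", 1:5))
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,(t4:1,t5:1):1):1);")
  dv <- distance_vectors(A, tree)
  expect_equal(length(dv$d1), choose(5, 2))
  hub <- apply(dv$pairs == "t1", 1, any)
  expect_true(all(dv$d1[hub] == 1))
  expect_true(all(dv$d1[!hub] == 2))
  # tree distances against an igraph BFS oracle on the tree graph
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  tipids <- as.character(seq_along(tree$tip.label))
  D <- igraph::distances(g, v = tipids, to = tipids)
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  for (k in seq_along(dv$d2)) {
    expect_equal(dv$d2[k], D[dv$pairs[k, 1], dv$pairs[k, 2]])
  }
  # disconnected node: pairs involving it are dropped
  A2 <- A; A2[1, 5] <- A2[5, 1] <- 0L
  dv2 <- distance_vectors(A2, tree)
  expect_equal(length(dv2$d1), choose(4, 2))
  expect_false(any(dv2$pairs == "t5"))
})

test_that("distance vectors are invariant to taxon reordering", {
  set.seed(121)
  p <- 8
  A <- (matrix(runif(p^2), p) < 0.3) * 1L
  A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0L
  nm <- paste0("t", 1:p)
  dimnames(A) <- list(nm, nm)
  tree <- ape::rtree(p, tip.label = sample(nm))
  dv1 <- distance_vectors(A, tree)
  pm <- sample(p)
  dv2 <- distance_vectors(A[pm, pm], tree)
  key <- function(dv) {
    k <- apply(dv$pairs, 1, function(r) paste(sort(r), collapse = "-"))
    ord <- order(k)
    list(k = k[ord], d1 = dv$d1[ord], d2 = dv$d2[ord])
  }
  expect_equal(key(dv1), key(dv2))
})

test_that("permutation test is near-degenerate when network mirrors tree", {
  set.seed(122)
  p <- 20
  tree <- ape::rtree(p, tip.label = paste0("t", 1:p))
  # network connects tips with small tree distance: strong concordance
  D <- lgnet:::tree_tip_distances(tree)
  A <- (D <= 4) * 1L; diag(A) <- 0L
  pt <- permutation_test(A, tree, n_perm = 99)
  expect_gt(pt$r0, 0.5)
  expect_lte(pt$p_value, 5 / 100)
})

test_that("permutation p-values have two-point support at n_perm = 1", {
  set.seed(123)
  p <- 10
  tree <- ape::rtree(p, tip.label = paste0("t", 1:p))
  A <- (matrix(runif(p^2), p) < 0.3) * 1L
  A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0L
  dimnames(A) <- list(paste0("t", 1:p), paste0("t", 1:p))
  ps <- replicate(20, permutation_test(A, tree, n_perm = 1)$p_value)
  expect_true(all(ps %in% c(0.5, 1)))
})

test_that("null correlations center near zero for balanced structures", {
  set.seed(124)
  p <- 15
  tree <- ape::rtree(p, tip.label = paste0("t", 1:p))
  A <- (matrix(runif(p^2), p) < 0.4) * 1L
  A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0L
  dimnames(A) <- list(paste0("t", 1:p), paste0("t", 1:p))
  pt <- permutation_test(A, tree, n_perm = 400)
  expect_lt(abs(mean(pt$null, na.rm = TRUE)), 0.05)
})
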
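# TPR/FPR, connection probabilities, ROC/AUC, baselines.

mk_adj <- function(p, pairs) {
  A <- matrix(0L, p, p)
  for (pr in pairs) { A[pr[1], pr[2]] <- 1L; A[pr[2], pr[1]] <- 1L }
  A
}

test_that("tpr_fpr counts undirected pairs once", {
  truth <- mk_adj(4, list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(unname(tpr_fpr(truth, truth)), c(1, 0))
  comp <- 1L - truth; diag(comp) <- 0L
  expect_equal(unname(tpr_fpr(comp, truth)), c(0, 1))
  est <- mk_adj(4, list(c(1, 2), c(2, 3), c(1, 4)))  # 2 true + 1 false
  expect_equal(unname(tpr_fpr(est, truth)), c(2 / 3, 1 / 3))
  empty <- matrix(0L, 4, 4)
  expect_error(tpr_fpr(est, empty), "no edges")
})

test_that("connection probabilities average within paths then replicates", {
  p <- 3
  A1 <- mk_adj(p, list(c(1, 2)))
  A0 <- matrix(0L, p, p)
  # replicate 1: proportions 0.4 (2 of 5 networks); replicate 2: 0.8
  rep1 <- c(replicate(2, A1, simplify = FALSE),
            replicate(3, A0, simplify = FALSE))
  rep2 <- c(replicate(4, A1, simplify = FALSE),
            replicate(1, A0, simplify = FALSE))
  pij <- connection_probabilities(list(rep1, rep2))
  expect_equal(pij[1, 2], 0.6)
  expect_equal(pij[1, 3], 0)
  all1 <- list(replicate(3, A1, simplify = FALSE))
  expect_equal(connection_probabilities(all1)[1, 2], 1)
})

test_that("AUC equals 1 for a perfect score and 0.5 for a constant", {
  truth <- mk_adj(4, list(c(1, 2), c(3, 4)))
  expect_equal(roc_auc(truth, truth)$auc, 1)
  expect_equal(roc_auc(matrix(0.3, 4, 4), truth)$auc, 0.5)
})

test_that("AUC equals the Mann-Whitney statistic on a hand toy", {
  truth <- mk_adj(4, list(c(1, 2), c(1, 3)))       # P = 2, N = 4
  S <- matrix(0, 4, 4)
  sc <- c("12" = 0.9, "13" = 0.4, "14" = 0.6, "23" = 0.2, "24" = 0.5,
          "34" = 0.1)
  S[1, 2] <- sc["12"]; S[1, 3] <- sc["13"]; S[1, 4] <- sc["14"]
  S[2, 3] <- sc["23"]; S[2, 4] <- sc["24"]; S[3, 4] <- sc["34"]
  S <- S + t(S)
  pos <- c(0.9, 0.4); neg <- c(0.6, 0.2, 0.5, 0.1)
  U <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(roc_auc(S, truth)$auc, U / (2 * 4))
})

test_that("trapezoid AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(111)
  p <- 12
  truth <- (matrix(runif(p * p), p) < 0.2) * 1L
  truth[lower.tri(truth)] <- t(truth)[lower.tri(truth)]
  diag(truth) <- 0L
  S <- matrix(runif(p * p), p); S <- (S + t(S)) / 2; diag(S) <- 0
  up <- upper.tri(truth)
  ours <- roc_auc(S, truth)$auc
  theirs <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(truth[up], S[up], direction = "<"))))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("glasso baseline equals the homogeneous fit on independent data", {
  set.seed(112)
  blocks <- lapply(1:40, function(i) {
    list(subject_id = as.character(i), times = 0, values = matrix(rnorm(4), 1))
  })
  d <- lgnet:::new_longitudinal_data(blocks, paste0("t", 1:4), center = TRUE)
  bg <- baseline_glasso(d, lambdas = 0.2, standardize = FALSE)
  fh <- suppressWarnings(sggm(d, lambda = 0.2))
  expect_equal(unname(bg$fits[[1]]$omega), unname(fh$omega), tolerance = 1e-8)
})

test_that("neighborhood AND and OR rules differ on an asymmetric toy", {
  # x3 = x1 + noise; x2 independent-ish: regression of x1 picks x3 and
  # vice versa, but weak cross-links appear in only one direction
  set.seed(113)
  n <- 60
  x1 <- rnorm(n); x3 <- x1 + 0.3 * rnorm(n); x2 <- rnorm(n) + 0.25 * x3
  df <- data.frame(subject_id = 1:n, time = 0, a = x1, b = x2, c = x3)
  d <- longitudinal_data(df)
  la <- baseline_neighborhood(d, nlambda = 12, rule = "AND")
  lo <- baseline_neighborhood(d, nlambda = 12, rule = "OR")
  n_and <- vapply(la$adjacencies, sum, numeric(1))
  n_or <- vapply(lo$adjacencies, sum, numeric(1))
  expect_true(any(n_or > n_and))
  expect_true(all(n_or >= n_and))
})

test_that("baseline paths are deterministic", {
  sim <- simulate_sggm(p = 8, m = 6, mean_ni = 5, edge_density = 0.25,
                       scenario = "homogeneous", tau = 0.1, seed = 114)
  b1 <- baseline_neighborhood(sim$data, nlambda = 5)
  b2 <- baseline_neighborhood(sim$data, nlambda = 5)
  expect_identical(b1$adjacencies, b2$adjacencies)
  g1 <- baseline_glasso(sim$data, nlambda = 5)
  g2 <- baseline_glasso(sim$data, nlambda = 5)
  expect_identical(g1$n_edges, g2$n_edges)
})
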
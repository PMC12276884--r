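# Synthetic-data engine: truth generation, observation times,
# Kronecker-structured draws, censoring.

test_that("generated precision matrices match their adjacency and are PD", {
  set.seed(91)
  for (method in c("gwishart", "dominance")) {
    tr <- generate_precision(30, 0.1, method = method)
    expect_equal(tr$adjacency, t(tr$adjacency))
    expect_equal(diag(tr$adjacency), rep(0L, 30))
    expect_gt(min(eigen(tr$omega, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    up <- upper.tri(tr$omega)
    expect_equal((abs(tr$omega[up]) > 1e-8) * 1L, tr$adjacency[up])
  }
})

test_that("realized edge counts sit in the binomial 99% band", {
  set.seed(92)
  tr <- generate_precision(80, 0.1)
  ne <- sum(tr$adjacency[upper.tri(tr$adjacency)])
  bounds <- qbinom(c(0.005, 0.995), choose(80, 2), 0.1)
  expect_gte(ne, bounds[1])
  expect_lte(ne, bounds[2])
})

test_that("observation times follow the truncated-Poisson gap design", {
  set.seed(93)
  tms <- generate_times(2000, mean_ni = 3)
  ni <- lengths(tms)
  expect_true(all(ni >= 2))
  gaps <- unlist(lapply(tms, diff))
  expect_true(all(gaps >= 0.5))
  expect_true(all(vapply(tms, function(t) t[1] == 0, logical(1))))
  # truncated-Poisson(3) mean, conditioned on >= 2
  k <- 0:100
  pk <- dpois(k, 3); pk[k < 2] <- 0; pk <- pk / sum(pk)
  expect_lt(abs(mean(ni) - sum(k * pk)), 0.05)
})

test_that("pooled covariance converges to Sigma in the independence limit", {
  set.seed(94)
  tr <- generate_precision(3, 0.3)
  sim <- simulate_sggm(p = 3, m = 400, mean_ni = 6, truth = tr,
                       scenario = "homogeneous", tau = 50)
  allv <- do.call(rbind, lapply(sim$data$subjects, `[[`, "values"))
  emp <- crossprod(allv) / nrow(allv)
  expect_lt(norm(emp - tr$sigma, "F") / norm(tr$sigma, "F"), 0.1)
})

test_that("lag-1 autocorrelation matches the exponential kernel", {
  set.seed(95)
  tr <- generate_precision(2, 0.3)
  tau <- 0.35
  # unit-spaced times via gap construction with min_gap dominating
  acc <- num <- 0
  for (i in 1:1500) {
    tms <- 0:5
    Y <- lgnet:::rmatnorm_kron(tms, tau, chol(tr$sigma))
    y <- Y[, 1] / sqrt(tr$sigma[1, 1])
    acc <- acc + sum(y[-1] * y[-6]); num <- num + 5
  }
  expect_equal(acc / num, exp(-tau), tolerance = 0.06)
})

test_that("empirical covariance of stacked draws approaches Phi kron Sigma", {
  set.seed(96)
  tr <- generate_precision(3, 0.3)
  tau <- 0.4; tms <- c(0, 1)
  K <- kronecker(build_phi(tau, tms), tr$sigma)
  n <- 2e4
  Y <- matrix(0, n, 6)
  U <- chol(tr$sigma)
  for (i in seq_len(n)) {
    Y[i, ] <- as.vector(t(lgnet:::rmatnorm_kron(tms, tau, U)))
  }
  emp <- crossprod(Y) / n
  expect_lt(norm(emp - K, "F") / norm(K, "F"), 0.05)
})

test_that("two-community data are independent across the split", {
  sim <- simulate_sggm(p = 40, m = 60, mean_ni = 6,
                       scenario = "two_community", tau = 0.018,
                       tau_B = 0.36, seed = 97)
  expect_equal(sim$truth$community, rep(c("A", "B"), each = 20))
  expect_equal(sum(abs(sim$truth$omega[1:20, 21:40])), 0)
  allv <- do.call(rbind, lapply(sim$data$subjects, `[[`, "values"))
  cors <- cor(allv)[1:20, 21:40]
  expect_lt(mean(abs(cors)), 0.08)
})

test_that("covariate scenario draws rates from the log-linear model", {
  sim <- simulate_sggm(p = 5, m = 3000, mean_ni = 2,
                       scenario = "covariate", coefs = c(4, 0, 0), seed = 98)
  expect_equal(dim(sim$truth$X), c(3000, 2))
  # E tau = exp(-4) when covariate effects are zero
  expect_equal(mean(sim$truth$tau_i), exp(-4), tolerance = 0.06)
})

test_that("left-censoring follows the quantile-replacement rule", {
  sim <- simulate_sggm(p = 4, m = 50, mean_ni = 6,
                       scenario = "homogeneous", tau = 0.1, seed = 99)
  d <- sim$data
  set.seed(100)
  d0 <- censor_left(d, 0.4, 0)
  expect_equal(as.data.frame(d0), as.data.frame(d))
  set.seed(101)
  d1 <- censor_left(d, 0.4, 1)
  allv0 <- do.call(rbind, lapply(d$subjects, `[[`, "values"))
  allv1 <- do.call(rbind, lapply(d1$subjects, `[[`, "values"))
  qs <- apply(allv0, 2, quantile, probs = 0.4)
  for (j in 1:4) expect_true(all(allv1[, j] >= pmin(qs[j], allv0[, j])))
  expect_true(all(allv1[allv0 >= rep(qs, each = nrow(allv0))] ==
                    allv0[allv0 >= rep(qs, each = nrow(allv0))]))
  # altered fraction ~ q1 * q2
  set.seed(102)
  d2 <- censor_left(d, 0.4, 0.5)
  allv2 <- do.call(rbind, lapply(d2$subjects, `[[`, "values"))
  expect_equal(mean(allv2 != allv0), 0.4 * 0.5, tolerance = 0.05)
})

test_that("simulation is fully reproducible under one seed", {
  s1 <- simulate_sggm(p = 6, m = 4, mean_ni = 4, scenario = "heterogeneous",
                      Etau = 0.05, censor = c(0.3, 0.5), seed = 103)
  s2 <- simulate_sggm(p = 6, m = 4, mean_ni = 4, scenario = "heterogeneous",
                      Etau = 0.05, censor = c(0.3, 0.5), seed = 103)
  expect_identical(s1$truth$omega, s2$truth$omega)
  expect_identical(as.data.frame(s1$data), as.data.frame(s2$data))
})
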
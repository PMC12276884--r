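# Temporal kernel, weighted second moments and likelihood identities.

test_that("build_phi matches the exponential kernel and its limits", {
  expect_equal(build_phi(Inf, c(0, 1, 2)), diag(3))
  expect_equal(build_phi(0.5, 0), matrix(1, 1, 1))
  ph <- build_phi(0.018, c(0, 1))
  expect_equal(ph[1, 2], exp(-0.018))
  expect_equal(diag(ph), c(1, 1))
  expect_error(build_phi(-1, c(0, 1)), "positive")
  expect_error(build_phi(0.5, c(0, NA)), "finite")
  expect_error(build_phi(0.5, c(1, 0)), "increasing")
  # positive definiteness across random settings
  set.seed(4)
  for (k in 1:20) {
    tms <- sort(runif(5, 0, 10))
    tau <- exp(runif(1, -4, 2))
    ev <- eigen(build_phi(tau, tms), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("phi_inverse gives the tridiagonal closed form", {
  # 2x2 closed form
  tau <- 0.7; dt <- 1.3
  rho <- exp(-tau * dt)
  pi2 <- phi_inverse(tau, c(0, dt))
  expect_equal(pi2$inverse,
               matrix(c(1, -rho, -rho, 1), 2) / (1 - rho^2), tolerance = 1e-12)
  expect_equal(pi2$logdet, log(1 - rho^2), tolerance = 1e-12)
  # independence limit
  pii <- phi_inverse(Inf, c(0, 1, 2))
  expect_equal(pii$inverse, diag(3))
  expect_equal(pii$logdet, 0)
  # dense linear-algebra oracle at n = 5
  set.seed(11)
  for (k in 1:10) {
    tms <- sort(runif(5, 0, 8))
    tau <- exp(runif(1, -3, 1))
    ph <- build_phi(tau, tms)
    piv <- phi_inverse(tau, tms)
    expect_equal(piv$inverse, solve(ph), tolerance = 1e-10)
    expect_equal(piv$logdet, as.numeric(determinant(ph)$modulus),
                 tolerance = 1e-10)
  }
  expect_error(phi_inverse(0, c(0, 1)), "positive")
})

test_that("s_matrix satisfies the Kronecker quadratic-form identity", {
  b1 <- random_block(1, 3, seed = 2)
  expect_equal(s_matrix(0.3, b1), tcrossprod(b1$values[1, ]))
  bI <- random_block(4, 2, seed = 3)
  expect_equal(s_matrix(Inf, bI), crossprod(bI$values))
  # tr(S_i(tau) Omega) == y' (Phi^-1 kron Omega) y on random instances
  set.seed(5)
  for (k in 1:25) {
    ni <- sample(2:4, 1); p <- sample(2:3, 1)
    b <- random_block(ni, p)
    om <- random_pd(p)
    tau <- exp(runif(1, -3, 1))
    lhs <- sum(s_matrix(tau, b) * om)
    y <- as.vector(t(b$values))
    rhs <- drop(t(y) %*% kronecker(solve(build_phi(tau, b$times)), om) %*% y)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("sbar pools subject matrices correctly", {
  d1 <- toy_dataset(m = 1, ni = 3, p = 2, seed = 7)
  expect_equal(sbar(0.4, d1), s_matrix(0.4, d1$subjects[[1]]) / 3)
  # all n_i = 1: empirical second-moment matrix for any tau
  set.seed(8)
  blocks <- lapply(1:4, function(i) {
    list(subject_id = as.character(i), times = 0,
         values = matrix(rnorm(3), 1))
  })
  d <- lgnet:::new_longitudinal_data(blocks, c("a", "b", "c"), center = FALSE)
  allv <- do.call(rbind, lapply(blocks, `[[`, "values"))
  expect_equal(unname(sbar(0.01, d)), unname(crossprod(allv) / 4))
  expect_equal(unname(sbar(7, d)), unname(crossprod(allv) / 4))
  # two subjects against a brute-force sum
  d2 <- toy_dataset(m = 2, ni = 2, p = 2, seed = 9)
  expect_equal(sbar(c(0.2, 0.9), d2),
               (s_matrix(0.2, d2$subjects[[1]]) +
                  s_matrix(0.9, d2$subjects[[2]])) / 4)
})

test_that("homogeneous log-likelihood equals the dense normal density", {
  # Omega = I, centered zero data, single observations -> 0
  blocks <- lapply(1:3, function(i) {
    list(subject_id = as.character(i), times = 0, values = matrix(0, 1, 2))
  })
  d0 <- lgnet:::new_longitudinal_data(blocks, c("a", "b"), center = FALSE)
  expect_equal(loglik_homogeneous(diag(2), 0.5, d0), 0)

  # oracle equivalence on 100 random small instances (constant-adjusted)
  set.seed(12)
  for (k in 1:100) {
    m <- sample(1:2, 1)
    blocks <- lapply(seq_len(m), function(i) {
      b <- random_block(sample(1:4, 1), 2)
      b$subject_id <- as.character(i)
      b
    })
    d <- lgnet:::new_longitudinal_data(blocks, c("a", "b"), center = FALSE)
    om <- random_pd(2)
    tau <- exp(runif(1, -3, 1))
    dense <- sum(vapply(blocks, dense_block_loglik, numeric(1),
                        omega = om, tau = tau))
    ours <- loglik_homogeneous(om, tau, d) - (d$n * d$p / 2) * log(2 * pi)
    expect_equal(ours, dense, tolerance = 1e-8)
  }
})

test_that("|Phi| increases toward independence as tau grows", {
  tms <- c(0, 0.8, 1.7, 3)
  lds <- vapply(c(0.05, 0.2, 1, 5), function(tau) {
    phi_inverse(tau, tms)$logdet
  }, numeric(1))
  expect_true(all(diff(lds) > 0))
})

test_that("tau posterior log-density matches term-by-term evaluation", {
  b <- random_block(3, 2, seed = 14)
  om <- random_pd(2, seed = 15)
  taus <- c(0.01, 0.1, 1, 10)
  got <- tau_posterior_logdensity(taus, b, om, alpha_i = 2)
  y <- as.vector(t(b$values))
  want <- vapply(taus, function(tau) {
    ph <- build_phi(tau, b$times)
    -(2 / 2) * as.numeric(determinant(ph)$modulus) -
      drop(t(y) %*% kronecker(solve(ph), om) %*% y) / 2 - 2 * tau
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)

  # single observation: linear in tau (prior only, up to constant)
  b1 <- random_block(1, 2, seed = 16)
  g <- tau_posterior_logdensity(taus, b1, om, alpha_i = 3)
  expect_equal(diff(g), -3 * diff(taus), tolerance = 1e-12)

  # finite near the lower tau bound
  expect_true(is.finite(tau_posterior_logdensity(1e-4, b, om, 1)))
  expect_error(tau_posterior_logdensity(-1, b, om, 1), "positive")
})

test_that("longitudinal_data validates and centers globally", {
  df <- data.frame(subject_id = rep(1:2, each = 3), time = rep(c(2, 0, 1), 2),
                   a = rnorm(6), b = rnorm(6))
  d <- longitudinal_data(df)
  expect_equal(d$m, 2L)
  expect_equal(d$subjects[[1]]$times, c(0, 1, 2))  # sorted
  allv <- do.call(rbind, lapply(d$subjects, `[[`, "values"))
  expect_equal(colMeans(allv), c(a = 0, b = 0), tolerance = 1e-12)

  dup <- df; dup$time <- rep(c(0, 0, 1), 2)
  expect_error(longitudinal_data(dup), "duplicate")
  bad <- df; bad$a[2] <- NA
  expect_error(longitudinal_data(bad), "finite|missing")
})
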
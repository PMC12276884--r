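# shared fixture builders; all randomness goes through an explicit seed

random_block <- function(ni, p, seed = NULL, gap_min = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  times <- cumsum(c(0, runif(ni - 1, gap_min, 2)))
  list(subject_id = "s1", times = times,
       values = matrix(rnorm(ni * p), ni, p))
}

random_pd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p)
}

toy_dataset <- function(m = 3, ni = 3, p = 2, seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_len(m), function(i) {
    b <- random_block(ni, p)
    b$subject_id <- as.character(i)
    b
  })
  lgnet:::new_longitudinal_data(blocks,
    taxon_names = sprintf("t%d", seq_len(p)), center = FALSE)
}

# dense multivariate-normal log-density oracle for one subject,
# covariance Phi kron solve(Omega)
dense_block_loglik <- function(block, omega, tau) {
  Sig <- kronecker(build_phi(tau, block$times), solve(omega))
  y <- as.vector(t(block$values))
  -0.5 * (length(y) * log(2 * pi) +
            as.numeric(determinant(Sig)$modulus) +
            drop(t(y) %*% solve(Sig) %*% y))
}
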
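# Shared fixtures and independent brute-force oracles used across tests.

# Random symmetric positive definite matrix, well conditioned.
rand_spd <- function(p, jitter = 0.5) {
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(jitter, p)
}

# Brute-force Benjamini-Hochberg step-up, written independently of the
# package: sort, scale by m/i, enforce monotonicity from the largest p.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Gaussian log density with diagonal covariance, coordinate by coordinate.
diag_mvn_logpdf <- function(y, vars) {
  sum(dnorm(y, mean = 0, sd = sqrt(vars), log = TRUE))
}

# All permutations of 1..n as a list (recursive, n small).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- combinat_perms(n - 1L)
  out <- list()
  for (perm in smaller) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(perm, n, after = pos)
    }
  }
  out
}

# Empirical rejection band: alpha +/- 3 binomial standard errors.
level_band <- function(alpha, n_reps) {
  alpha + c(-3, 3) * sqrt(alpha * (1 - alpha) / n_reps)
}

expect_within <- function(x, band) {
  expect_gte(x, band[1])
  expect_lte(x, band[2])
}
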
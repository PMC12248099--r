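test_that("mean difference and pooled covariance match hand computations", {
  set.seed(201)
  x1 <- matrix(rnorm(5 * 4), 5, 4)
  x2 <- matrix(rnorm(3 * 4), 3, 4)
  dm <- difference_of_means(x1, x2)
  loop <- sapply(seq_len(4), function(j) mean(x1[, j]) - mean(x2[, j]))
  expect_equal(dm$y, loop, tolerance = 1e-12)
  expect_equal(difference_of_means(matrix(rnorm(100), 50, 2),
                                   matrix(rnorm(100), 50, 2))$eta, 0.04)
  # identical samples give a zero difference
  expect_equal(difference_of_means(x1, x1)$y, rep(0, 4))

  # scalar pooled variance oracle at p = 1, n1 = n2 = 2
  a <- matrix(c(1, 3), 2, 1); b <- matrix(c(2, 6), 2, 1)
  hand <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (2 + 2 - 2)
  expect_equal(pooled_covariance(a, b)[1, 1], hand)
  # constant samples give the zero matrix; random S is PSD
  cst <- matrix(1, 4, 3)
  expect_equal(pooled_covariance(cst, 2 * cst), matrix(0, 3, 3))
  S <- pooled_covariance(x1, x2)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(pooled_covariance(x1[1, , drop = FALSE], x2[1, , drop = FALSE]),
               "n1 \\+ n2")
})

test_that("oracle FAB statistic equals a diagonal closed-form log ratio", {
  # p = 2 diagonal case: densities are products of univariate normals
  Sigma <- diag(c(2, 0.5))
  E <- matrix(c(1, 0), 2, 1)
  prior <- spiked_prior(E, nu = 3, gamma = 0.2)
  eta <- 0.1
  y <- c(0.7, -1.3)
  # null variances eta*diag(Sigma); marginal adds Psi = diag(3 + .2, .2)
  hand <- diag_mvn_logpdf(y, eta * diag(Sigma) + c(3.2, 0.2)) -
    diag_mvn_logpdf(y, eta * diag(Sigma))
  expect_equal(t_fab_oracle(y, Sigma, prior, eta), hand, tolerance = 1e-12)

  # prior collapsing to the null sends the statistic to zero
  tiny <- spiked_prior(E, nu = 1e-14, gamma = 1e-14)
  expect_lt(abs(t_fab_oracle(y, Sigma, tiny, eta)), 1e-10)

  # monotone in ||y|| along a fixed direction when Sigma = I
  set.seed(202)
  E2 <- matrix(rnorm(8), 4, 2)
  pr <- spiked_prior(E2, 1, 0.5)
  dir <- rnorm(4)
  vals <- sapply(c(0.5, 1, 2, 4), function(c) {
    t_fab_oracle(c * dir, diag(4), pr, 0.2)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("oracle statistic is an affine function of its quadratic form", {
  set.seed(203)
  p <- 6
  Sigma <- rand_spd(p)
  prior <- spiked_prior(matrix(rnorm(p * 2), p, 2), 1.5, 0.3)
  ys <- replicate(6, rnorm(p))
  llr <- apply(ys, 2, t_fab_oracle, Sigma = Sigma, prior = prior, eta = 0.07)
  quad <- apply(ys, 2, t_fab_quadratic, Sigma = Sigma, prior = prior,
                eta = 0.07)
  slopes <- diff(llr) / diff(quad)
  expect_equal(slopes, rep(0.5, 5), tolerance = 1e-8)
})

test_that("oracle null matches the weighted chi-square construction", {
  set.seed(204)
  p <- 7; eta <- 0.05
  Sigma <- rand_spd(p)
  E <- matrix(rnorm(p * 2), p, 2)
  prior <- spiked_prior(E, 2, 0.4)
  Psi <- 2 * tcrossprod(E) + 0.4 * diag(p)
  es <- eigen(Sigma, symmetric = TRUE)
  Sh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  lambda <- eigen(Sh %*% solve(Psi) %*% Sh, symmetric = TRUE)$values
  w <- 1 / (eta * lambda + 1)
  n_mc <- 4000
  # package route: simulate y ~ N(0, eta*Sigma) and evaluate the quadratic
  R <- chol(eta * Sigma)
  qs_pkg <- replicate(n_mc, {
    y <- as.numeric(crossprod(R, rnorm(p)))
    t_fab_quadratic(y, Sigma, prior, eta)
  })
  # independent construction: weighted sum of chi-square(1) draws
  qs_chi <- colSums(w * matrix(rchisq(n_mc * p, df = 1), p, n_mc))
  expect_gt(ks.test(qs_pkg, qs_chi)$p.value, 0.01)
})

test_that("Monte Carlo null quantile is exact in one dimension", {
  # p = 1: statistic is 0.5*w*chi2_1 + const with a closed-form quantile
  Sigma <- matrix(1.7); E <- matrix(0.9); eta <- 0.3
  prior <- spiked_prior(E, nu = 2, gamma = 0.1)
  psi <- 2 * 0.81 + 0.1
  lam <- 1.7 / psi
  w <- 1 / (eta * lam + 1)
  const <- 0.5 * (log(eta * 1.7) - log(eta * 1.7 + psi))
  q_pkg <- oracle_null_quantile(Sigma, prior, eta, alpha = 0.05,
                                n_mc = 60000, seed = 5)
  q_exact <- 0.5 * w * qchisq(0.95, df = 1) + const
  # bound = 3 asymptotic standard errors of the order statistic
  dens <- dchisq(qchisq(0.95, 1), 1) / (0.5 * w)
  se <- sqrt(0.95 * 0.05 / 60000) / dens
  expect_lt(abs(q_pkg - q_exact), 3 * se)
  # alpha -> 1 returns the sample minimum
  ns <- oracle_null_quantile(Sigma, prior, eta, alpha = 1 - 1e-12,
                             n_mc = 500, seed = 6)
  expect_equal(ns, oracle_null_quantile(Sigma, prior, eta, alpha = 0.999999,
                                        n_mc = 500, seed = 6),
               tolerance = 1e-6)
  expect_warning(oracle_null_quantile(Sigma, prior, eta, n_mc = 50, seed = 1),
                 "rough")
})

test_that("rejecting at the oracle null quantile achieves its level", {
  set.seed(205)
  p <- 5; eta <- 0.08
  Sigma <- rand_spd(p)
  prior <- spiked_prior(matrix(rnorm(p * 2), p, 2), 1, 0.2)
  q95 <- oracle_null_quantile(Sigma, prior, eta, alpha = 0.05,
                              n_mc = 10000, seed = 7)
  R <- chol(eta * Sigma)
  n_test <- 5000
  rej <- mean(replicate(n_test, {
    y <- as.numeric(crossprod(R, rnorm(p)))
    t_fab_oracle(y, Sigma, prior, eta) > q95
  }))
  expect_within(rej, level_band(0.05, n_test))
})

test_that("limiting statistic is a projection statistic", {
  set.seed(206)
  p <- 10; d <- 3
  E <- matrix(rnorm(p * d), p, d)
  Sigma <- rand_spd(p)
  y <- rnorm(p)
  # invariance under E -> E G for random invertible G
  for (i in 1:5) {
    G <- matrix(rnorm(d * d), d, d) + diag(d)
    expect_equal(t_lfab(y, Sigma, E %*% G), t_lfab(y, Sigma, E),
                 tolerance = 1e-10)
  }
  # Sigma = I, orthonormal E: squared norm of the projection
  Q <- qr.Q(qr(E))
  expect_equal(t_lfab(y, diag(p), Q), sum(crossprod(Q, y)^2),
               tolerance = 1e-10)
  # y orthogonal to the column space of Sigma^{-1}E gives zero
  A <- solve(Sigma, E)
  y_perp <- residuals(lm.fit(A, rnorm(p)))
  expect_lt(t_lfab(y_perp, Sigma, E), 1e-12)
  expect_error(t_lfab(y, Sigma, cbind(E, E[, 1])), "rank deficient")
})

test_that("limiting statistic is the diffuse-prior limit of the oracle", {
  set.seed(207)
  p <- 20; d <- 4; eta <- 0.04
  Sigma <- rand_spd(p)
  E <- matrix(rnorm(p * d), p, d)
  prior <- spiked_prior(E, nu = 1e8, gamma = 1e-8)
  ys <- replicate(50, rnorm(p))
  t_or <- apply(ys, 2, t_fab_oracle, Sigma = Sigma, prior = prior, eta = eta)
  t_lf <- apply(ys, 2, t_lfab, Sigma = Sigma, E = E)
  # affine map estimated on two probe points
  a <- (t_or[2] - t_or[1]) / (t_lf[2] - t_lf[1])
  b <- t_or[1] - a * t_lf[1]
  rel_err <- abs(a * t_lf + b - t_or) / diff(range(t_or))
  expect_lt(max(rel_err), 1e-3)
})

test_that("projected Hotelling statistic matches explicit matrix products", {
  set.seed(208)
  p <- 8; d <- 3; n1 <- 12; n2 <- 9
  x1 <- matrix(rnorm(n1 * p), n1, p)
  x2 <- matrix(rnorm(n2 * p), n2, p)
  E <- matrix(rnorm(p * d), p, d)
  St <- rand_spd(p)
  dm <- difference_of_means(x1, x2)
  S <- pooled_covariance(x1, x2)
  A <- solve(St, E)
  brute <- (n1 * n2 / (n1 + n2)) *
    drop(t(dm$y) %*% A %*% solve(t(A) %*% S %*% A, t(A) %*% dm$y))
  expect_equal(t_afab(dm$y, S, E, n1, n2, Sigma_tilde = St), brute,
               tolerance = 1e-10)
  # identity whitening + orthonormal E reduces to the projected norm
  Q <- qr.Q(qr(E))
  expect_equal(t_afab(dm$y, diag(p), Q, n1, n2),
               (n1 * n2 / (n1 + n2)) * sum(crossprod(Q, dm$y)^2),
               tolerance = 1e-10)
  # d = p with E = I is the classical Hotelling T-squared
  hotelling <- (n1 * n2 / (n1 + n2)) *
    drop(t(dm$y) %*% solve(S, dm$y))
  expect_equal(t_afab(dm$y, S, diag(p), n1, n2), hotelling, tolerance = 1e-10)
  # invariance to E -> E G
  G <- matrix(rnorm(d * d), d, d) + 2 * diag(d)
  expect_equal(t_afab(dm$y, S, E %*% G, n1, n2, Sigma_tilde = St),
               t_afab(dm$y, S, E, n1, n2, Sigma_tilde = St),
               tolerance = 1e-9)
  S_small <- pooled_covariance(x1[1:2, ], x2[1:2, ]) # rank 2 < p
  expect_error(t_afab(dm$y, S_small, diag(p), 2, 2), "singular")
})

test_that("F p-value scaling follows the exact null characterization", {
  expect_equal(afab_pvalue(0, 10, 12, 3), 1)
  # n1 = n2 = 50, d = 10: scaling constant 89/980
  Tstat <- (980 / 89) * qf(0.95, 10, 89)
  expect_equal(afab_pvalue(Tstat, 50, 50, 10), 0.05, tolerance = 1e-12)
  expect_error(afab_pvalue(1, 3, 2, 5), "n1 \\+ n2")
})

test_that("shrinkage whitening matrix has the prescribed ridge", {
  set.seed(209)
  p <- 10
  x1 <- matrix(rnorm(12 * p), 12, p)
  x2 <- matrix(rnorm(8 * p), 8, p)
  St <- shrinkage_sigma_tilde(x1, x2)
  ridge <- p / (10 * 20)
  expect_equal(St, pooled_covariance(x1, x2) + diag(ridge, p),
               tolerance = 1e-12)
  # zero-variance held-out data leaves only the ridge
  cst1 <- matrix(2, 12, p); cst2 <- matrix(5, 8, p)
  expect_equal(shrinkage_sigma_tilde(cst1, cst2), diag(ridge, p))
  # eigenvalues bounded below by the ridge coefficient
  expect_gte(min(eigen(St, symmetric = TRUE, only.values = TRUE)$values),
             ridge - 1e-10)
  # single-row held-out sample: covariance from the other sample alone
  St1 <- shrinkage_sigma_tilde(x1, x2[1, , drop = FALSE])
  expect_equal(St1, cov(x1) + diag(p / (10 * 13), p), tolerance = 1e-12)
})

test_that("split-sample variant allocates ceiling(r n) rows and accepts the r grid", {
  set.seed(210)
  p <- 12; d <- 3
  E <- matrix(rnorm(p * d), p, d)
  x1 <- matrix(rnorm(50 * p), 50, p)
  x2 <- matrix(rnorm(50 * p), 50, p)
  for (r in c(0.5, 0.66, 0.8)) {
    ht <- fab_two_sample(x1, x2, E, variant = "split", r = r, seed = 4)
    m <- ceiling(r * 50)
    # the F denominator df reveals the test-set size: 2m - d - 1
    expect_equal(unname(ht$parameter["df_den"]), 2 * m - d - 1)
    expect_true(ht$p.value >= 0 && ht$p.value <= 1)
  }
  # r = 0.66, n = 50 gives a 33 / 17 split
  expect_equal(ceiling(0.66 * 50), 33)
  expect_error(fab_two_sample(x1[1:2, ], x2, E, variant = "split", r = 0.9),
               "split fraction")
})

test_that("single treated profile uses the control covariance and shifted df", {
  set.seed(211)
  p <- 15; d <- 4; n1 <- 30
  E <- matrix(rnorm(p * d), p, d)
  x1 <- matrix(rnorm(n1 * p), n1, p)
  x2 <- matrix(rnorm(p), 1, p)
  ht <- fab_two_sample(x1, x2, E, variant = "naive")
  expect_equal(unname(ht$parameter["df_den"]), n1 + 1 - d - 1)
  # statistic built from the control-only covariance
  y <- colMeans(x1) - as.numeric(x2)
  S1 <- cov(x1)
  brute <- (n1 / (n1 + 1)) * drop(t(y) %*% E %*% solve(t(E) %*% S1 %*% E,
                                                       t(E) %*% y))
  expect_equal(unname(ht$statistic), brute, tolerance = 1e-10)
})

test_that("random projection test is seeded and reduces to Hotelling at d = p", {
  set.seed(212)
  p <- 6; n1 <- 15; n2 <- 15
  x1 <- matrix(rnorm(n1 * p), n1, p)
  x2 <- matrix(rnorm(n2 * p), n2, p)
  h1 <- fab_two_sample(x1, x2, variant = "rp", d = 3, seed = 8)
  h2 <- fab_two_sample(x1, x2, variant = "rp", d = 3, seed = 8)
  expect_identical(h1$p.value, h2$p.value)
  # identity projection hook equals the classical Hotelling p-value
  hid <- fab_two_sample(x1, x2, variant = "rp", projection = diag(p))
  dm <- difference_of_means(x1, x2)
  S <- pooled_covariance(x1, x2)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(dm$y) %*% solve(S, dm$y))
  p_hot <- pf((n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T2, p,
              n1 + n2 - p - 1, lower.tail = FALSE)
  expect_equal(hid$p.value, p_hot, tolerance = 1e-12)
})

test_that("oracle variant rejects by Monte Carlo null and is reproducible", {
  set.seed(213)
  p <- 5
  Sigma <- rand_spd(p)
  E <- matrix(rnorm(p * 2), p, 2)
  dat <- simulate_two_sample(Sigma, rep(0, p), 10, 10, seed = 3)
  h1 <- fab_two_sample(dat$x1, dat$x2, E, variant = "oracle", Sigma = Sigma,
                       nu = 1, gamma = 0.2, n_mc = 2000, seed = 11)
  h2 <- fab_two_sample(dat$x1, dat$x2, E, variant = "oracle", Sigma = Sigma,
                       nu = 1, gamma = 0.2, n_mc = 2000, seed = 11)
  expect_identical(h1$p.value, h2$p.value)
  expect_true(h1$p.value > 0 && h1$p.value <= 1)
  expect_error(fab_two_sample(dat$x1, dat$x2, E, variant = "oracle"),
               "requires")
})

test_that("whitening with the true covariance is no less powerful than identity", {
  # paired comparison on signals in the embedding column space
  set.seed(214)
  p <- 50; d <- 5; n1 <- 15; n2 <- 15
  E <- matrix(rnorm(p * d), p, d)
  Sigma <- make_covariance(p, decay_power = 5, total_variance = p / 2,
                           seed = 21)
  delta <- as.numeric(E %*% rnorm(d)); delta <- 0.45 * delta / sqrt(sum(delta^2))
  reps <- 400
  rej <- matrix(0L, reps, 2)
  for (i in seq_len(reps)) {
    dat <- simulate_two_sample(Sigma, delta, n1, n2, seed = 3000 + i)
    dm <- difference_of_means(dat$x1, dat$x2)
    S <- pooled_covariance(dat$x1, dat$x2)
    t_id <- t_afab(dm$y, S, E, n1, n2)
    t_tr <- t_afab(dm$y, S, E, n1, n2, Sigma_tilde = Sigma)
    rej[i, ] <- c(afab_pvalue(t_id, n1, n2, d) <= 0.05,
                  afab_pvalue(t_tr, n1, n2, d) <= 0.05)
  }
  diff_hat <- mean(rej[, 2]) - mean(rej[, 1])
  se <- sd(rej[, 2] - rej[, 1]) / sqrt(reps)
  expect_gte(diff_hat, -2 * se)
})
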
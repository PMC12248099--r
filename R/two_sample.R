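#' Spiked prior over signal directions
#'
#' Constructs the Gaussian prior covariance specification
#' `Psi = nu * E %*% t(E) + gamma * I_p` used by the embedding-informed
#' tests. As `nu / gamma` grows the prior concentrates its mass near the
#' column space of the embedding matrix `E`.
#'
#' @param E numeric `p x d` embedding (or score) matrix.
#' @param nu nonnegative scalar weight on the embedding component.
#' @param gamma nonnegative isotropic component; `gamma > 0` makes the prior
#'   covariance positive definite.
#' @return an object of class `"spiked_prior"` (list with `E`, `nu`,
#'   `gamma`).
#' @export
spiked_prior <- function(E, nu, gamma) {
  E <- as.matrix(E)
  storage.mode(E) <- "double"
  stopifnot(is.numeric(nu), length(nu) == 1L, nu >= 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  if (!all(is.finite(E))) stop("`E` has non-finite entries", call. = FALSE)
  structure(list(E = E, nu = nu, gamma = gamma), class = "spiked_prior")
}

#' @export
print.spiked_prior <- function(x, ...) {
  cat("Spiked Gaussian prior: p =", nrow(x$E), ", d =", ncol(x$E),
      ", nu =", x$nu, ", gamma =", x$gamma, "\n")
  invisible(x)
}

#' Difference of sample means and its variance multiplier
#'
#' For two samples of p-dimensional profiles, returns the difference of the
#' sample mean vectors `y = colMeans(x1) - colMeans(x2)` -- the sufficient
#' statistic for the mean difference when the common covariance is known --
#' together with `eta = 1/n1 + 1/n2`, the factor by which the common
#' covariance is scaled in the distribution of `y`.
#'
#' @param x1,x2 numeric matrices with observations in rows and the same
#'   number of columns (genes).
#' @return list with `y` (length p), `eta`, `n1`, `n2`.
#' @export
difference_of_means <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("samples must have the same number of columns",
                                 call. = FALSE)
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 1L || n2 < 1L) stop("each sample needs at least one observation",
                               call. = FALSE)
  list(y = colMeans(x1) - colMeans(x2), eta = 1 / n1 + 1 / n2,
       n1 = n1, n2 = n2)
}

#' Pooled sample covariance of two samples
#'
#' `S = (1/(n1+n2-2)) * sum_j sum_i (x_ij - xbar_j)(x_ij - xbar_j)'`. A
#' sample with a single row contributes nothing to the sum (its mean is the
#' row itself) but still counts in the degrees of freedom; use
#' `df = "available"` to divide instead by the number of rows actually
#' contributing deviations minus the number of contributing samples (the
#' convention for a treated sample of size one, where only controls inform
#' the covariance).
#'
#' @inheritParams difference_of_means
#' @param df either `"pooled"` (divisor `n1+n2-2`) or `"available"`.
#' @return a symmetric positive semidefinite `p x p` matrix.
#' @export
pooled_covariance <- function(x1, x2, df = c("pooled", "available")) {
  df <- match.arg(df)
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("samples must have the same number of columns",
                                 call. = FALSE)
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 + n2 < 3L) stop("need n1 + n2 >= 3 observations for a pooled covariance",
                         call. = FALSE)
  c1 <- if (n1 > 1L) sweep(x1, 2L, colMeans(x1)) else NULL
  c2 <- if (n2 > 1L) sweep(x2, 2L, colMeans(x2)) else NULL
  cc <- rbind(c1, c2)
  divisor <- switch(df,
    pooled = n1 + n2 - 2L,
    available = (if (n1 > 1L) n1 - 1L else 0L) + (if (n2 > 1L) n2 - 1L else 0L))
  if (divisor < 1L) stop("insufficient replication for a covariance estimate",
                         call. = FALSE)
  S <- crossprod(cc) / divisor
  (S + t(S)) / 2
}

#' Oracle FAB statistic for the two-sample mean test
#'
#' The exact log likelihood ratio of the marginal density of `y` under the
#' spiked prior against its null density: `log N(y; 0, eta*Sigma + Psi) -
#' log N(y; 0, eta*Sigma)` with `Psi = nu E E' + gamma I`. This is an
#' increasing affine function of the quadratic form
#' [t_fab_quadratic()], so either form induces the same test; the log-ratio
#' form is the one whose Monte Carlo null [oracle_null_quantile()] uses.
#'
#' @param y difference of sample means (length p).
#' @param Sigma known `p x p` positive definite covariance of a single
#'   profile.
#' @param prior a [spiked_prior()]; `gamma > 0` is required so the prior
#'   covariance is invertible.
#' @param eta variance multiplier `1/n1 + 1/n2`.
#' @return scalar log likelihood ratio.
#' @export
t_fab_oracle <- function(y, Sigma, prior, eta) {
  stopifnot(inherits(prior, "spiked_prior"), eta > 0)
  y <- as.numeric(y)
  Psi <- spiked_prior_matrix(prior$E, prior$nu, prior$gamma)
  null_part <- spd_logdet_quad(eta * Sigma, y)
  alt_part <- spd_logdet_quad(eta * Sigma + Psi, y)
  0.5 * (null_part$logdet - alt_part$logdet +
           null_part$quad - alt_part$quad)
}

#' Quadratic-form rendering of the oracle FAB statistic
#'
#' `y' [ (eta*Sigma)^{-1} - (eta*Sigma + Psi)^{-1} ] y`: the data-dependent
#' part of [t_fab_oracle()] (the log ratio equals half this quadratic plus a
#' constant not involving `y`). Exposed for cross-checking; under the null
#' it is distributed as a weighted sum of independent chi-squared(1)
#' variables with weights `1/(eta*lambda_j + 1)`, `lambda_j` the
#' eigenvalues of `Sigma^{1/2} Psi^{-1} Sigma^{1/2}`.
#'
#' @inheritParams t_fab_oracle
#' @return nonnegative scalar.
#' @export
t_fab_quadratic <- function(y, Sigma, prior, eta) {
  stopifnot(inherits(prior, "spiked_prior"), eta > 0)
  y <- as.numeric(y)
  Psi <- spiked_prior_matrix(prior$E, prior$nu, prior$gamma)
  spd_logdet_quad(eta * Sigma, y)$quad -
    spd_logdet_quad(eta * Sigma + Psi, y)$quad
}

#' Monte Carlo null quantile of the oracle FAB statistic
#'
#' Draws `y ~ N_p(0, eta*Sigma)` and returns the empirical `1 - alpha`
#' quantile of [t_fab_oracle()] over the draws. Rejecting when the observed
#' statistic exceeds this quantile gives a level-`alpha` test when `Sigma`
#' is the true covariance.
#'
#' @inheritParams t_fab_oracle
#' @param alpha test level in (0, 1).
#' @param n_mc number of Monte Carlo draws; fewer than 100 triggers a
#'   warning.
#' @param seed optional integer seed.
#' @return scalar empirical quantile.
#' @export
oracle_null_quantile <- function(Sigma, prior, eta, alpha = 0.05,
                                 n_mc = 10000L, seed = NULL) {
  stats::quantile(oracle_null_sample(Sigma, prior, eta, n_mc, seed),
                  probs = 1 - alpha, names = FALSE)
}

# Sorted sample of null oracle statistics (shared by quantile and p-value).
oracle_null_sample <- function(Sigma, prior, eta, n_mc, seed = NULL) {
  stopifnot(inherits(prior, "spiked_prior"), eta > 0)
  n_mc <- check_count(n_mc, "n_mc", min = 2L)
  if (n_mc < 100L) warning("n_mc < 100 gives a very rough null quantile",
                           call. = FALSE)
  p <- nrow(Sigma)
  Psi <- spiked_prior_matrix(prior$E, prior$nu, prior$gamma)
  M0 <- eta * ((Sigma + t(Sigma)) / 2)
  M1 <- M0 + Psi
  R0 <- chol(M0)
  ch1 <- chol((M1 + t(M1)) / 2)
  const <- 2 * sum(log(diag(R0))) - 2 * sum(log(diag(ch1)))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_mc * p), p, n_mc)
    Y <- crossprod(R0, Z)               # columns ~ N(0, eta*Sigma)
    q0 <- colSums(Z^2)
    W <- forwardsolve(t(ch1), Y)
    q1 <- colSums(W^2)
    sort(0.5 * (const + q0 - q1))
  })
}

#' Limiting FAB statistic for the two-sample mean test
#'
#' The diffuse-prior limit of the oracle FAB test (prior mass entirely on
#' the embedding column space): `T = y' A (A' Sigma A)^{-1} A' y` with
#' `A = Sigma^{-1} E`. A projection statistic -- it depends on `E` only
#' through its column space and is invariant to `E %*% G` for invertible
#' `G`.
#'
#' @inheritParams t_fab_oracle
#' @param E `p x d` embedding matrix of full column rank.
#' @return nonnegative scalar.
#' @export
t_lfab <- function(y, Sigma, E) {
  E <- as.matrix(E)
  y <- as.numeric(y)
  rk <- qr(E)$rank
  if (rk < ncol(E)) {
    stop("`E` is rank deficient (rank ", rk, " < d = ", ncol(E), ")",
         call. = FALSE)
  }
  A <- sym_solve(Sigma, E)          # Sigma^{-1} E
  z <- crossprod(A, y)              # A' y
  B <- crossprod(E, A)              # A' Sigma A = E' Sigma^{-1} E
  as.numeric(crossprod(z, sym_solve(B, z)))
}

#' Embedding-projected Hotelling statistic
#'
#' The practical approximation to the limiting FAB statistic:
#' `T = (n1*n2/(n1+n2)) * y' A (A' S A)^{-1} A' y` with
#' `A = Sigma_tilde^{-1} E`, where `S` is the pooled sample covariance and
#' `Sigma_tilde` a whitening matrix chosen independently of `y` and `S`
#' (identity for the naive variant). Equivalent to a classical Hotelling
#' T-squared computed on the d-dimensional projected data.
#'
#' @param y difference of sample means.
#' @param S pooled sample covariance on `n1 + n2 - 2` degrees of freedom.
#' @param E `p x d` embedding matrix.
#' @param n1,n2 the sample sizes used to form `y` and `S`.
#' @param Sigma_tilde whitening matrix; `NULL` (default) means the identity.
#' @return nonnegative scalar statistic.
#' @export
t_afab <- function(y, S, E, n1, n2, Sigma_tilde = NULL) {
  E <- as.matrix(E)
  y <- as.numeric(y)
  A <- if (is.null(Sigma_tilde)) E else sym_solve(Sigma_tilde, E)
  z <- crossprod(A, y)
  M <- crossprod(A, S %*% A)
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps))) {
    stop("projected covariance A' S A is singular: need covariance degrees ",
         "of freedom (", n1 + n2 - 2L, ") comfortably above d = ", ncol(E),
         call. = FALSE)
  }
  w <- forwardsolve(t(ch), z)
  (n1 * n2 / (n1 + n2)) * sum(w^2)
}

#' Exact F p-value for the projected Hotelling statistic
#'
#' When the projection is independent of the data, the scaled statistic
#' `((n1+n2-d-1) / (d*(n1+n2-2))) * T` follows an exact
#' `F(d, n1+n2-d-1)` null distribution; this returns its upper-tail
#' probability.
#'
#' @param T statistic from [t_afab()].
#' @param n1,n2 sample sizes used to form the mean difference and pooled
#'   covariance.
#' @param d projection dimension.
#' @return p-value in `[0, 1]`.
#' @export
afab_pvalue <- function(T, n1, n2, d) {
  d <- check_count(d, "d")
  if (n1 + n2 <= d + 1L) {
    stop("need n1 + n2 > d + 1 for the F null (n1+n2 = ", n1 + n2,
         ", d = ", d, ")", call. = FALSE)
  }
  scale <- (n1 + n2 - d - 1) / (d * (n1 + n2 - 2))
  stats::pf(scale * T, d, n1 + n2 - d - 1, lower.tail = FALSE)
}

#' Shrinkage whitening matrix from held-out observations
#'
#' `Sigma_tilde = S_held + (p / (10 * n_held)) * I_p`, where `S_held` is the
#' pooled covariance of the held-out observations and `n_held` their total
#' count. The ridge term keeps the estimate positive definite in the
#' `p > n_held` regime. If one held-out sample has fewer than two rows the
#' pooled covariance is computed from the other sample alone; if neither
#' sample has two rows the estimate degenerates to the ridge alone (with a
#' warning).
#'
#' @inheritParams difference_of_means
#' @return a symmetric positive definite `p x p` matrix.
#' @export
shrinkage_sigma_tilde <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  n_held <- n1 + n2
  if (n_held < 1L) stop("held-out set is empty", call. = FALSE)
  p <- ncol(x1)
  ridge <- p / (10 * n_held)
  if (n1 < 2L && n2 < 2L) {
    warning("no held-out sample has >= 2 rows; whitening matrix is the ",
            "ridge alone", call. = FALSE)
    return(diag(ridge, p))
  }
  S <- if (n1 >= 2L && n2 >= 2L) {
    pooled_covariance(x1, x2)
  } else if (n1 >= 2L) {
    stats::cov(x1)
  } else {
    stats::cov(x2)
  }
  S + diag(ridge, p)
}

#' Embedding-informed two-sample mean tests
#'
#' Tests the hypothesis of equal mean vectors in two samples of
#' p-dimensional profiles, concentrating power on the column space of an
#' embedding matrix `E`. Four variants:
#' \describe{
#'   \item{`"naive"`}{projected Hotelling test with identity whitening
#'     (`Sigma_tilde = I`); uses all observations for the mean difference
#'     and pooled covariance.}
#'   \item{`"split"`}{split-sample variant: a seeded shuffle assigns the
#'     first `ceiling(r * n_j)` observations of each sample to the mean
#'     difference and pooled covariance, and the remainder to a shrinkage
#'     whitening matrix ([shrinkage_sigma_tilde()]), restoring the exact F
#'     null while whitening toward the true covariance.}
#'   \item{`"rp"`}{random-projection baseline: an i.i.d. Gaussian `p x d`
#'     projection replaces `E`.}
#'   \item{`"oracle"`}{exact FAB likelihood-ratio test for known `Sigma`
#'     with a Monte Carlo null (requires `Sigma`, `nu`, `gamma`).}
#' }
#' A treated sample of a single row is supported (screen convention): the
#' covariance is then estimated from the other sample alone and the F
#' degrees of freedom use the effective total `n1 + n2`.
#'
#' @inheritParams difference_of_means
#' @param E `p x d` embedding matrix (ignored for `variant = "rp"` unless
#'   supplied as the projection hook).
#' @param variant one of `"naive"`, `"split"`, `"rp"`, `"oracle"`.
#' @param d projection dimension for `"rp"` (defaults to `ncol(E)`).
#' @param r split fraction in (0, 1) for `"split"`.
#' @param Sigma true covariance, required for `"oracle"`.
#' @param nu,gamma spiked-prior weights for `"oracle"`.
#' @param n_mc Monte Carlo size for the `"oracle"` null.
#' @param seed integer seed controlling the split shuffle, the random
#'   projection, and the oracle Monte Carlo.
#' @param projection optional explicit `p x d` projection matrix for
#'   `variant = "rp"` (testing hook).
#' @return an object of class `"htest"`.
#' @examples
#' set.seed(1)
#' E <- matrix(rnorm(40 * 4), 40, 4)
#' x1 <- matrix(rnorm(25 * 40), 25, 40)
#' x2 <- matrix(rnorm(25 * 40), 25, 40)
#' fab_two_sample(x1, x2, E, variant = "naive")
#' @export
fab_two_sample <- function(x1, x2, E = NULL,
                           variant = c("naive", "split", "rp", "oracle"),
                           d = NULL, r = 0.66, Sigma = NULL,
                           nu = NULL, gamma = NULL, n_mc = 10000L,
                           seed = NULL, projection = NULL) {
  dname <- paste(deparse1(substitute(x1)), "vs", deparse1(substitute(x2)))
  variant <- match.arg(variant)
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  if (ncol(x2) != p) stop("samples must have the same number of columns",
                          call. = FALSE)

  if (variant == "oracle") {
    if (is.null(Sigma) || is.null(E) || is.null(nu) || is.null(gamma)) {
      stop("variant = \"oracle\" requires Sigma, E, nu and gamma",
           call. = FALSE)
    }
    dm <- difference_of_means(x1, x2)
    prior <- spiked_prior(E, nu, gamma)
    stat <- t_fab_oracle(dm$y, Sigma, prior, dm$eta)
    null_sorted <- oracle_null_sample(Sigma, prior, dm$eta, n_mc, seed)
    pval <- (1 + sum(null_sorted >= stat)) / (1 + length(null_sorted))
    return(new_htest(
      statistic = c("T_FAB" = stat), parameter = c(n_mc = n_mc),
      p.value = pval,
      method = "Oracle FAB two-sample mean test (Monte Carlo null)",
      data.name = dname))
  }

  if (variant == "rp") {
    if (is.null(d)) d <- if (!is.null(projection)) ncol(projection)
                         else if (!is.null(E)) ncol(E)
                         else stop("specify d for the random-projection test",
                                   call. = FALSE)
    P <- if (!is.null(projection)) as.matrix(projection) else
      with_seed(seed, matrix(stats::rnorm(p * d), p, d))
    res <- projected_hotelling(x1, x2, P)
    return(new_htest(
      statistic = c("T_RP" = res$stat),
      parameter = c(df_num = res$d, df_den = res$df_den),
      p.value = res$p,
      method = sprintf("Random-projection Hotelling test (d = %d)", res$d),
      data.name = dname))
  }

  if (is.null(E)) stop("an embedding matrix `E` is required", call. = FALSE)
  E <- as.matrix(E)
  if (nrow(E) != p) stop("nrow(E) must equal the number of genes (columns ",
                         "of the samples)", call. = FALSE)

  if (variant == "naive") {
    res <- projected_hotelling(x1, x2, E)
    return(new_htest(
      statistic = c("T_AFAB" = res$stat),
      parameter = c(df_num = res$d, df_den = res$df_den),
      p.value = res$p,
      method = sprintf("Naive AFAB two-sample test (d = %d, identity whitening)",
                       res$d),
      data.name = dname))
  }

  # split-sample variant
  if (!(r > 0 && r < 1)) stop("`r` must lie in (0, 1)", call. = FALSE)
  m1 <- as.integer(ceiling(r * n1)); m2 <- as.integer(ceiling(r * n2))
  if (m1 < 1L || m2 < 1L || m1 >= n1 || m2 >= n2) {
    stop("split fraction r = ", r, " leaves an empty test or held-out set ",
         "(n1 = ", n1, ", n2 = ", n2, ")", call. = FALSE)
  }
  idx <- with_seed(seed, list(i1 = sample.int(n1), i2 = sample.int(n2)))
  x1_test <- x1[idx$i1[seq_len(m1)], , drop = FALSE]
  x2_test <- x2[idx$i2[seq_len(m2)], , drop = FALSE]
  x1_held <- x1[idx$i1[-seq_len(m1)], , drop = FALSE]
  x2_held <- x2[idx$i2[-seq_len(m2)], , drop = FALSE]
  Sig_t <- shrinkage_sigma_tilde(x1_held, x2_held)
  res <- projected_hotelling(x1_test, x2_test, E, Sigma_tilde = Sig_t)
  new_htest(
    statistic = c("T_AFAB" = res$stat),
    parameter = c(df_num = res$d, df_den = res$df_den),
    p.value = res$p,
    method = sprintf(
      "Split-sample AFAB two-sample test (d = %d, r = %g, shrinkage whitening)",
      res$d, r),
    data.name = dname)
}

# Shared mechanics: mean difference, covariance (with the single-row-sample
# convention), projected Hotelling statistic and exact F p-value.
projected_hotelling <- function(x1, x2, E, Sigma_tilde = NULL) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 + n2 < 3L) stop("need n1 + n2 >= 3 observations", call. = FALSE)
  dm <- difference_of_means(x1, x2)
  S <- if (min(n1, n2) >= 2L) pooled_covariance(x1, x2)
       else pooled_covariance(x1, x2, df = "available")
  stat <- t_afab(dm$y, S, E, n1, n2, Sigma_tilde = Sigma_tilde)
  d <- ncol(as.matrix(E))
  list(stat = stat, p = afab_pvalue(stat, n1, n2, d), d = d,
       df_den = n1 + n2 - d - 1L)
}
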
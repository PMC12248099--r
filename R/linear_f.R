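#' Self-normalize a response profile
#'
#' Divides a response vector by its Euclidean norm, producing a point on the
#' unit sphere. Under the global null of no linear relationship with the
#' design (and Gaussian errors of any variance), the normalized profile is
#' uniform on the sphere, which removes the unknown error variance from the
#' testing problem.
#'
#' @param x numeric vector with positive norm.
#' @return unit vector of the same length.
#' @export
self_normalize <- function(x) {
  x <- as.numeric(x)
  nx <- sqrt(sum(x^2))
  if (!is.finite(nx) || nx == 0) stop("`x` must have positive finite norm",
                                      call. = FALSE)
  x / nx
}

#' FAB statistic for the linear hypothesis
#'
#' For the model `x ~ N_n(G theta, sigma^2 I)` with spiked prior
#' `theta ~ N_p(0, nu E E' + gamma I)` and a point-mass value
#' `sigma_tilde_sq` for the error variance, the FAB statistic evaluated at
#' the self-normalized profile `y = x / ||x||` is
#' `-n * log( y' (G Psi G' + sigma_tilde_sq I)^{-1} y )`.
#'
#' @param y unit-norm response profile of length `n` (use
#'   [self_normalize()]).
#' @param G `n x p` design matrix (e.g. baseline expression of `p` genes in
#'   `n` cell lines).
#' @param prior a [spiked_prior()] on the p-dimensional coefficient vector.
#' @param sigma_tilde_sq positive point-mass value for the error variance;
#'   guarantees invertibility.
#' @return scalar statistic (large values indicate departure from the
#'   null).
#' @export
fab_f_statistic <- function(y, G, prior, sigma_tilde_sq) {
  stopifnot(inherits(prior, "spiked_prior"), sigma_tilde_sq > 0)
  y <- as.numeric(y)
  G <- as.matrix(G)
  n <- nrow(G)
  if (length(y) != n) stop("length(y) must equal nrow(G)", call. = FALSE)
  if (abs(sum(y^2) - 1) > 1e-8) {
    stop("`y` must be unit norm; apply self_normalize() first", call. = FALSE)
  }
  M <- fab_f_kernel(G, prior, sigma_tilde_sq)
  -n * log(spd_logdet_quad(M, y)$quad)
}

# G Psi G' + sigma_tilde_sq I assembled without forming the p x p prior:
# nu (GE)(GE)' + gamma G G' + sigma_tilde_sq I.
fab_f_kernel <- function(G, prior, sigma_tilde_sq) {
  n <- nrow(G)
  H <- G %*% prior$E
  M <- prior$nu * tcrossprod(H) + diag(sigma_tilde_sq, n)
  if (prior$gamma > 0) M <- M + prior$gamma * tcrossprod(G)
  (M + t(M)) / 2
}

#' Monte Carlo null sample for the FAB linear statistic
#'
#' Simulates `x ~ N_n(0, I)`, self-normalizes, and evaluates
#' [fab_f_statistic()]; because the null distribution of the normalized
#' profile is uniform on the sphere, this sample is the exact null for any
#' error variance. The level-`alpha` test rejects when the observed
#' statistic exceeds the empirical `1 - alpha` quantile.
#'
#' @inheritParams fab_f_statistic
#' @param n_mc number of draws (>= 100).
#' @param seed optional integer seed.
#' @return sorted numeric vector of `n_mc` null statistics.
#' @export
fab_f_mc_null <- function(G, prior, sigma_tilde_sq, n_mc = 10000L,
                          seed = NULL) {
  n_mc <- check_count(n_mc, "n_mc", min = 100L)
  G <- as.matrix(G)
  n <- nrow(G)
  M <- fab_f_kernel(G, prior, sigma_tilde_sq)
  ch <- chol(M)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_mc * n), n, n_mc)
    Z <- sweep(Z, 2L, sqrt(colSums(Z^2)), "/")
    W <- forwardsolve(t(ch), Z)
    sort(-n * log(colSums(W^2)))
  })
}

#' FAB F-test for a linear hypothesis
#'
#' Tests `H: theta = 0` in `x ~ N_n(G theta, sigma^2 I)` with power
#' concentrated near the embedding column space. Two modes:
#' \describe{
#'   \item{`"limit"`}{(default) the diffuse-prior limit: an exact classical
#'     global F-test of the regression of `x` on the reduced `n x d` design
#'     `G %*% E`, with `(d, n - d)` degrees of freedom. Free of the error
#'     variance and of `(nu, gamma)`.}
#'   \item{`"mc"`}{the finite-prior FAB statistic with a Monte Carlo null on
#'     the sphere; requires `nu`, `gamma` and a point-mass error variance
#'     (default: the sample variance of `x`, which only affects power, not
#'     level).}
#' }
#' No intercept is added; set `center = TRUE` to mean-center `x` and the
#' columns of `G` first.
#'
#' @param x response vector of length `n` (e.g. viability scores).
#' @param G `n x p` design matrix.
#' @param E `p x d` embedding matrix, `d < n`.
#' @param mode `"limit"` or `"mc"`.
#' @param nu,gamma spiked-prior weights (mode `"mc"`).
#' @param sigma_tilde_sq point-mass error variance for mode `"mc"`;
#'   defaults to `var(x)`.
#' @param n_mc Monte Carlo size for mode `"mc"`.
#' @param seed integer seed for the Monte Carlo null.
#' @param center mean-center `x` and the columns of `G` first.
#' @return an object of class `"htest"`.
#' @examples
#' set.seed(2)
#' G <- matrix(rnorm(50 * 12), 50, 12)
#' E <- matrix(rnorm(12 * 3), 12, 3)
#' x <- rnorm(50)
#' fab_ftest(x, G, E)
#' @export
fab_ftest <- function(x, G, E, mode = c("limit", "mc"), nu = 1, gamma = 1e-4,
                      sigma_tilde_sq = NULL, n_mc = 10000L, seed = NULL,
                      center = FALSE) {
  dname <- deparse1(substitute(x))
  mode <- match.arg(mode)
  x <- as.numeric(x)
  G <- as.matrix(G)
  E <- as.matrix(E)
  if (center) {
    x <- x - mean(x)
    G <- scale(G, center = TRUE, scale = FALSE)
  }
  if (mode == "limit") {
    return(limiting_fab_f_test(x, G, E, data.name = dname))
  }
  prior <- spiked_prior(E, nu, gamma)
  if (is.null(sigma_tilde_sq)) sigma_tilde_sq <- stats::var(x)
  y <- self_normalize(x)
  stat <- fab_f_statistic(y, G, prior, sigma_tilde_sq)
  null_sorted <- fab_f_mc_null(G, prior, sigma_tilde_sq, n_mc = n_mc,
                               seed = seed)
  pval <- (1 + sum(null_sorted >= stat)) / (1 + length(null_sorted))
  new_htest(statistic = c("F_FAB" = stat), parameter = c(n_mc = n_mc),
            p.value = pval,
            method = sprintf(
              "FAB F-test, Monte Carlo null (nu = %g, gamma = %g)", nu, gamma),
            data.name = dname)
}

#' Limiting FAB F-test (exact F null on the reduced design)
#'
#' The diffuse-prior limit of the FAB F-test: a classical global F-test of
#' `H: beta = 0` in `x ~ N_n(G E beta, sigma^2 I)`, i.e. the no-intercept
#' regression of `x` on the `n x d` reduced design `G %*% E`, with
#' `(d, n - d)` degrees of freedom.
#'
#' @inheritParams fab_ftest
#' @param data.name label for printing.
#' @return an object of class `"htest"` with the F statistic, degrees of
#'   freedom and exact p-value.
#' @export
limiting_fab_f_test <- function(x, G, E, data.name = deparse1(substitute(x))) {
  force(data.name)
  x <- as.numeric(x)
  H <- as.matrix(G) %*% as.matrix(E)
  global_f(x, H, data.name = data.name,
           method = "Limiting FAB F-test on the embedding-reduced design")
}

#' Classical global F-test
#'
#' The textbook global F-test of `H: theta = 0` for the no-intercept model
#' `x ~ N_n(G theta, sigma^2 I)`, with `(p, n - p)` degrees of freedom;
#' requires `n > p`. In gene-expression designs where `p` approaches `n`
#' this test has little power -- the regime the embedding-reduced test is
#' designed for.
#'
#' @inheritParams fab_ftest
#' @return an object of class `"htest"`.
#' @export
classical_f_test <- function(x, G) {
  dname <- deparse1(substitute(x))
  x <- as.numeric(x)
  G <- as.matrix(G)
  if (nrow(G) <= ncol(G)) {
    stop("classical F-test needs n > p (n = ", nrow(G), ", p = ", ncol(G),
         "); use the embedding-reduced test in this regime", call. = FALSE)
  }
  global_f(x, G, data.name = dname,
           method = "Classical global F-test (no intercept)")
}

# Global F of the no-intercept regression of x on design H (n x d).
global_f <- function(x, H, data.name, method) {
  n <- nrow(H)
  qh <- qr(H)
  d <- qh$rank
  if (d < ncol(H)) {
    stop("design is rank deficient (effective rank ", d, " < ", ncol(H), ")",
         call. = FALSE)
  }
  if (d >= n) stop("need more observations than regressors (n = ", n,
                   ", d = ", d, ")", call. = FALSE)
  fitted <- qr.fitted(qh, x)
  rss1 <- sum((x - fitted)^2)
  ess <- sum(fitted^2)
  if (rss1 <= .Machine$double.eps * sum(x^2)) {
    # exact fit: report an unbounded statistic with a zero p-value
    return(new_htest(statistic = c("F" = Inf),
                     parameter = c(df_num = d, df_den = n - d),
                     p.value = 0, method = paste(method, "(exact fit)"),
                     data.name = data.name))
  }
  stat <- (ess / d) / (rss1 / (n - d))
  new_htest(statistic = c("F" = stat),
            parameter = c(df_num = d, df_den = n - d),
            p.value = stats::pf(stat, d, n - d, lower.tail = FALSE),
            method = method, data.name = data.name)
}

#' Batch F-tests over a matrix of response profiles
#'
#' Applies [fab_ftest()] (and optionally [classical_f_test()]) to each
#' column of a response matrix and appends Benjamini-Hochberg adjusted
#' q-values -- the screening workflow for a library of perturbations.
#'
#' @param X `n x K` matrix of response profiles, one column per
#'   perturbation.
#' @inheritParams fab_ftest
#' @param classical also compute the classical global F-test per column
#'   (requires `n > p`).
#' @return a data frame with one row per column of `X`: `unit_id`,
#'   `statistic`, `df_num`, `df_den`, `p_value`, `q_value`, and classical
#'   counterparts when requested.
#' @export
fab_ftest_batch <- function(X, G, E, mode = c("limit", "mc"),
                            classical = FALSE, ...) {
  X <- as.matrix(X)
  mode <- match.arg(mode)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("unit", seq_len(ncol(X)))
  res <- lapply(seq_len(ncol(X)), function(j) {
    ht <- fab_ftest(X[, j], G, E, mode = mode, ...)
    data.frame(unit_id = ids[j], statistic = unname(ht$statistic),
               df_num = unname(ht$parameter["df_num"]),
               df_den = unname(ht$parameter["df_den"]),
               p_value = ht$p.value)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  if (classical) {
    pc <- vapply(seq_len(ncol(X)), function(j) classical_f_test(X[, j], G)$p.value,
                 numeric(1L))
    out$p_classical <- pc
    out$q_classical <- bh_adjust(pc)
  }
  rownames(out) <- NULL
  out
}
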
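# Internal numerical helpers shared across the test modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the caller's RNG stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Symmetrize, then solve M x = b via Cholesky; fall back to an
# eigen-decomposition with a small eigenvalue floor when M is numerically
# indefinite. Used for every SPD solve so failures are handled uniformly.
sym_solve <- function(M, b, eig_floor = 1e-12) {
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, forwardsolve(t(ch), b)))
  }
  warning("Cholesky factorization failed; falling back to eigen-decomposition ",
          "with eigenvalue floor ", format(eig_floor), call. = FALSE)
  ee <- eigen(M, symmetric = TRUE)
  vals <- pmax(ee$values, eig_floor)
  ee$vectors %*% ((crossprod(ee$vectors, b)) / vals)
}

# log|M| and the quadratic form y' M^{-1} y for symmetric positive definite M.
spd_logdet_quad <- function(M, y) {
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ee <- eigen(M, symmetric = TRUE)
    if (any(ee$values <= 0)) {
      stop("matrix is numerically singular (min eigenvalue ",
           format(min(ee$values)), ")", call. = FALSE)
    }
    z <- crossprod(ee$vectors, y)
    return(list(logdet = sum(log(ee$values)),
                quad = sum(z^2 / ee$values)))
  }
  z <- forwardsolve(t(ch), y)
  list(logdet = 2 * sum(log(diag(ch))), quad = sum(z^2))
}

# Prior covariance Psi = nu E E' + gamma I applied implicitly.
spiked_prior_matrix <- function(E, nu, gamma) {
  stopifnot(is.matrix(E), nu >= 0, gamma >= 0)
  p <- nrow(E)
  nu * tcrossprod(E) + diag(gamma, p)
}

# Multivariate normal draws: n x p matrix with rows N(mu, Sigma) given a
# pre-computed upper-triangular chol factor of Sigma.
rmvnorm_chol <- function(n, mu, chol_sigma) {
  p <- ncol(chol_sigma)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol_sigma
  sweep(z, 2L, mu, "+")
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

new_htest <- function(statistic, parameter, p.value, method, data.name,
                      estimate = NULL, ...) {
  out <- list(statistic = statistic, parameter = parameter,
              p.value = p.value, method = method, data.name = data.name,
              estimate = estimate, ...)
  out <- out[!vapply(out, is.null, logical(1L))]
  class(out) <- "htest"
  out
}
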
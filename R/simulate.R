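#' Random covariance with controlled spectral decay
#'
#' Builds a `p x p` covariance whose eigenvalues are an equi-spaced
#' sequence of `p` numbers between 0.1 and 1 raised to `decay_power`
#' (20 for fast decay, 5 for slow), normalized so the trace equals
#' `total_variance`, with Haar-random eigenvectors.
#'
#' @param p dimension.
#' @param decay_power exponent applied to the equi-spaced base sequence.
#' @param total_variance target trace (default 50).
#' @param seed optional integer seed.
#' @return a symmetric positive definite `p x p` matrix with attribute
#'   `"eigenvalues"` (nonincreasing).
#' @export
make_covariance <- function(p, decay_power, total_variance = 50,
                            seed = NULL) {
  p <- check_count(p, "p")
  stopifnot(decay_power > 0, total_variance > 0)
  ev <- seq(0.1, 1, length.out = p)^decay_power
  ev <- ev * (total_variance / sum(ev))
  ev <- rev(ev)                                 # nonincreasing
  V <- sample_haar_orthogonal(p, seed = seed)
  Sigma <- V %*% (ev * t(V))
  Sigma <- (Sigma + t(Sigma)) / 2
  attr(Sigma, "eigenvalues") <- ev
  Sigma
}

#' Random Gaussian embedding matrix and its principal basis
#'
#' Draws a `p x d` matrix with i.i.d. standard normal entries -- the
#' synthetic stand-in for a text-derived gene embedding matrix -- together
#' with the orthonormal basis of its column space (left singular vectors).
#'
#' @param p number of genes.
#' @param d embedding dimension.
#' @param seed optional integer seed.
#' @return list with `E` (`p x d`) and `U` (orthonormal `p x d`).
#' @export
make_embedding_basis <- function(p, d, seed = NULL) {
  p <- check_count(p, "p"); d <- check_count(d, "d")
  if (d > p) stop("need d <= p", call. = FALSE)
  with_seed(seed, {
    E <- matrix(stats::rnorm(p * d), p, d)
    list(E = E, U = svd(E, nu = d, nv = 0L)$u)
  })
}

#' Unit-norm signal concentrated near an embedding subspace
#'
#' Simulates `z ~ N_d(0, I)`, then `v ~ N_p(U z, gamma_noise * I)` and
#' returns `delta = v / ||v||`. Small `gamma_noise` places the signal
#' almost exactly in the subspace spanned by `U`; the realized alignment
#' `||U' delta||^2` is reported.
#'
#' @param U orthonormal `p x d` basis (e.g. from
#'   [make_embedding_basis()]).
#' @param gamma_noise positive isotropic noise variance.
#' @param seed optional integer seed.
#' @return list with unit vector `delta` and scalar `alignment`.
#' @export
make_signal <- function(U, gamma_noise, seed = NULL) {
  U <- basis_of(U)
  stopifnot(gamma_noise > 0)
  p <- nrow(U); d <- ncol(U)
  with_seed(seed, {
    z <- stats::rnorm(d)
    v <- as.numeric(U %*% z) + stats::rnorm(p, sd = sqrt(gamma_noise))
    delta <- v / sqrt(sum(v^2))
    list(delta = delta, alignment = sum(crossprod(U, delta)^2))
  })
}

#' Simulate a Gaussian two-sample dataset
#'
#' Sample 1 rows are `N_p(0, Sigma)`, sample 2 rows `N_p(delta, Sigma)`
#' (signal added to the treated sample).
#'
#' @param Sigma `p x p` positive definite covariance.
#' @param delta mean-difference vector (length p); 0 gives null data.
#' @param n1,n2 sample sizes.
#' @param seed optional integer seed.
#' @return list with matrices `x1` (`n1 x p`) and `x2` (`n2 x p`).
#' @export
simulate_two_sample <- function(Sigma, delta, n1, n2, seed = NULL) {
  n1 <- check_count(n1, "n1"); n2 <- check_count(n2, "n2")
  Sigma <- (Sigma + t(Sigma)) / 2
  # steeply decaying spectra are numerically PSD only: use an eigen square
  # root with flooring when the Cholesky factorization refuses
  R <- tryCatch(chol(Sigma), error = function(e) {
    ee <- eigen(Sigma, symmetric = TRUE)
    t(ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors)))
  })
  p <- ncol(R)
  delta <- rep_len(as.numeric(delta), p)
  with_seed(seed, {
    list(x1 = rmvnorm_chol(n1, rep(0, p), R),
         x2 = rmvnorm_chol(n2, delta, R))
  })
}

#' Simulation scenario for the two-sample power study
#'
#' Bundles the study conditions: dimension, embedding dimension, sample
#' sizes, spectral-decay exponents, signal-noise levels, split fractions
#' and replication counts. The defaults are the full-scale study
#' conditions (`p = 200`, `d = 10`, `n1 = n2 = 50`, fast/slow decay 20/5,
#' trace 50, noise `1, 2/3, 1/3`, split fractions `0.5, 0.66, 0.8`, 15
#' instances of 100 realizations); every field can be overridden, e.g. for
#' a scaled-down run.
#'
#' @param p,d,n1,n2 dimensions and sample sizes.
#' @param decay_power spectral-decay exponents to study.
#' @param gamma_noise signal-noise variances to study.
#' @param total_variance covariance trace.
#' @param r_grid split fractions for the split-sample variant.
#' @param n_instances random (Sigma, delta) instances per cell.
#' @param n_realizations datasets per instance.
#' @param seed base seed; instance `i` of cell `c` uses a deterministic
#'   offset so every cell is independently reproducible.
#' @return a list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(p = 200L, d = 10L, n1 = 50L, n2 = 50L,
                                decay_power = c(20, 5),
                                gamma_noise = c(1, 2 / 3, 1 / 3),
                                total_variance = 50,
                                r_grid = c(0.5, 0.66, 0.8),
                                n_instances = 15L, n_realizations = 100L,
                                seed = 1L) {
  sc <- list(p = check_count(p, "p"), d = check_count(d, "d"),
             n1 = check_count(n1, "n1"), n2 = check_count(n2, "n2"),
             decay_power = decay_power, gamma_noise = gamma_noise,
             total_variance = total_variance, r_grid = r_grid,
             n_instances = check_count(n_instances, "n_instances"),
             n_realizations = check_count(n_realizations, "n_realizations"),
             seed = check_count(seed, "seed", min = 0L))
  if (sc$d > sc$p) stop("need d <= p", call. = FALSE)
  if (any(sc$gamma_noise <= 0)) stop("gamma_noise must be positive",
                                     call. = FALSE)
  class(sc) <- "simulation_scenario"
  sc
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("Two-sample power-study scenario\n")
  cat("  p =", x$p, ", d =", x$d, ", n1 =", x$n1, ", n2 =", x$n2, "\n")
  cat("  decay_power:", paste(x$decay_power, collapse = ", "),
      " gamma_noise:", paste(signif(x$gamma_noise, 3), collapse = ", "), "\n")
  cat("  split fractions:", paste(x$r_grid, collapse = ", "), "\n")
  cat("  ", x$n_instances, "instances x", x$n_realizations,
      "realizations, base seed", x$seed, "\n")
  invisible(x)
}

#' Power study for the two-sample tests
#'
#' For each combination of spectral decay and signal-noise level, draws
#' `n_instances` random pairs (Sigma, delta) -- with one embedding matrix
#' `E` fixed per study -- and, for each instance, estimates the power of
#' the requested tests as the rejection proportion over `n_realizations`
#' simulated datasets.
#'
#' @param scenario a [simulation_scenario()].
#' @param methods subset of `"afab_naive"`, `"afab_ss"`, `"rp"`.
#' @param alpha test level.
#' @param null_override if `TRUE`, force `delta = 0` (calibration mode; the
#'   reported "power" is then the empirical type I error).
#' @param redraw_embedding draw a fresh `E` per instance instead of fixing
#'   one per study.
#' @return data frame with columns `decay`, `gamma_noise`, `method`, `r`
#'   (`NA` except for the split-sample variant), `instance`, `alignment`,
#'   `power`.
#' @export
power_study <- function(scenario, methods = c("afab_naive", "afab_ss", "rp"),
                        alpha = 0.05, null_override = FALSE,
                        redraw_embedding = FALSE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  methods <- match.arg(methods, c("afab_naive", "afab_ss", "rp"),
                       several.ok = TRUE)
  sc <- scenario
  eb <- make_embedding_basis(sc$p, sc$d, seed = sc$seed)
  arms <- study_arms(methods, sc$r_grid, sc$n1, sc$n2)
  rows <- list()
  cell_id <- 0L
  for (q in sc$decay_power) {
    for (gn in sc$gamma_noise) {
      cell_id <- cell_id + 1L
      for (i in seq_len(sc$n_instances)) {
        inst_seed <- sc$seed + 1000L * cell_id + i
        Sigma <- make_covariance(sc$p, q, sc$total_variance,
                                 seed = inst_seed)
        if (redraw_embedding) {
          eb <- make_embedding_basis(sc$p, sc$d, seed = inst_seed + 500L)
        }
        sig <- make_signal(eb$U, gn, seed = inst_seed + 1L)
        delta <- if (null_override) rep(0, sc$p) else sig$delta
        rej <- matrix(0L, sc$n_realizations, length(arms))
        for (s in seq_len(sc$n_realizations)) {
          dat <- simulate_two_sample(Sigma, delta, sc$n1, sc$n2,
                                     seed = inst_seed + 10L * s)
          for (a in seq_along(arms)) {
            arm <- arms[[a]]
            ht <- fab_two_sample(dat$x1, dat$x2, E = eb$E,
                                 variant = arm$variant, d = sc$d,
                                 r = arm$r, seed = inst_seed + 10L * s + a)
            rej[s, a] <- as.integer(ht$p.value <= alpha)
          }
        }
        for (a in seq_along(arms)) {
          rows[[length(rows) + 1L]] <- data.frame(
            decay = q, gamma_noise = gn, method = arms[[a]]$label,
            r = arms[[a]]$r_out, instance = i,
            alignment = sig$alignment, power = mean(rej[, a]))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

study_arms <- function(methods, r_grid, n1, n2) {
  arms <- list()
  if ("afab_naive" %in% methods) {
    arms[[length(arms) + 1L]] <- list(variant = "naive", r = 0.66,
                                      r_out = NA_real_, label = "afab_naive")
  }
  if ("afab_ss" %in% methods) {
    for (r in r_grid) {
      m1 <- ceiling(r * n1); m2 <- ceiling(r * n2)
      if (m1 < 1 || m2 < 1 || m1 >= n1 || m2 >= n2) {
        message("skipping infeasible split fraction r = ", r)
        next
      }
      arms[[length(arms) + 1L]] <- list(variant = "split", r = r, r_out = r,
                                        label = "afab_ss")
    }
  }
  if ("rp" %in% methods) {
    arms[[length(arms) + 1L]] <- list(variant = "rp", r = 0.66,
                                      r_out = NA_real_, label = "rp")
  }
  if (!length(arms)) stop("no feasible study arms", call. = FALSE)
  arms
}

#' Null inputs for the linear F-test
#'
#' A standard-normal response (global null, any error variance is
#' equivalent after self-normalization) and an i.i.d. Gaussian design.
#'
#' @param n,p design dimensions.
#' @param seed optional integer seed.
#' @return list with `x` (length n) and `G` (`n x p`).
#' @export
simulate_linear_null <- function(n, p, seed = NULL) {
  n <- check_count(n, "n"); p <- check_count(p, "p")
  with_seed(seed, list(x = stats::rnorm(n),
                       G = matrix(stats::rnorm(n * p), n, p)))
}

#' Synthetic replicate panel for the scalar FAB t-tests
#'
#' Draws gene effects `theta ~ N_K(0, nu E E' + gamma I)` for a Gaussian
#' embedding `E`, then replicate-level measurements
#' `x_ijk ~ N(mu_jk, sigma^2)` with `mu_1k = 0`, `mu_2k = theta_k`.
#'
#' @param K number of genes.
#' @param d embedding dimension.
#' @param nu,gamma prior weights generating the effects (`nu = 0` gives
#'   independent coordinates; both 0 gives the global null).
#' @param n1,n2 replicates per condition.
#' @param sigma per-measurement error sd.
#' @param seed optional integer seed.
#' @return list with `x1`, `x2` (replicate matrices), `E`, and the true
#'   `theta`.
#' @export
simulate_scalar_panel <- function(K, d, nu, gamma, n1 = 4L, n2 = 4L,
                                  sigma = 1, seed = NULL) {
  K <- check_count(K, "K"); d <- check_count(d, "d")
  n1 <- check_count(n1, "n1"); n2 <- check_count(n2, "n2")
  stopifnot(nu >= 0, gamma >= 0, sigma > 0)
  with_seed(seed, {
    E <- matrix(stats::rnorm(K * d), K, d)
    theta <- sqrt(nu) * as.numeric(E %*% stats::rnorm(d)) +
      sqrt(gamma) * stats::rnorm(K)
    x1 <- matrix(stats::rnorm(n1 * K, sd = sigma), n1, K)
    x2 <- matrix(stats::rnorm(n2 * K, sd = sigma), n2, K, byrow = FALSE) +
      matrix(theta, n2, K, byrow = TRUE)
    list(x1 = x1, x2 = x2, E = E, theta = theta)
  })
}
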
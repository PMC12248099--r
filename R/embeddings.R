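#' Standardize an embedding matrix and reduce it to principal scores
#'
#' Centers and scales each embedding coordinate (column), then returns the
#' first `d` principal score vectors `U_d %*% diag(s_d)`, whose column space
#' equals that of the best rank-`d` approximation of the standardized matrix.
#' This is the usual preprocessing applied to large text-derived gene
#' embedding matrices (for example a genes x 1536 matrix of language-model
#' embeddings) before they are used as a prior subspace.
#'
#' Columns with zero variance carry no information about gene-gene geometry
#' and are dropped with a warning before the decomposition.
#'
#' @param E numeric matrix, genes in rows and embedding coordinates in
#'   columns; row names (gene identifiers) are preserved.
#' @param d number of principal components to retain, at most `min(dim(E))`.
#' @param standardize if `TRUE` (default) center each column to mean 0 and
#'   scale to standard deviation 1 (denominator `p - 1`) first.
#' @return a numeric `p x d` matrix of principal scores with the input's row
#'   names.
#' @seealso [principal_basis()], [subspace_alignment()]
#' @export
reduce_embeddings <- function(E, d, standardize = TRUE) {
  E <- as_embedding_matrix(E)
  if (standardize) E <- standardize_columns(E)
  d <- check_count(d, "d")
  if (d > min(dim(E))) {
    stop("`d` (", d, ") exceeds min(dim(E)) = ", min(dim(E)), call. = FALSE)
  }
  sv <- svd(E, nu = d, nv = 0L)
  scores <- fix_signs(sv$u) %*% diag(sv$d[seq_len(d)], d)
  rownames(scores) <- rownames(E)
  scores
}

#' Principal subspace of an embedding matrix
#'
#' Computes the first `k` left singular vectors of `E` (columns ordered by
#' nonincreasing singular value), the orthonormal basis of the principal
#' embedding subspace on which the FAB tests concentrate power.
#'
#' @inheritParams reduce_embeddings
#' @param k subspace dimension, at most `min(dim(E))`.
#' @return a list of class `"principal_subspace"` with elements `basis`
#'   (`p x k`, orthonormal columns) and `values` (the first `k` singular
#'   values, nonincreasing).
#' @export
principal_basis <- function(E, k) {
  E <- as_embedding_matrix(E)
  k <- check_count(k, "k")
  if (k > min(dim(E))) {
    stop("`k` (", k, ") exceeds min(dim(E)) = ", min(dim(E)), call. = FALSE)
  }
  sv <- svd(E, nu = k, nv = 0L)
  out <- list(basis = fix_signs(sv$u), values = sv$d[seq_len(k)])
  rownames(out$basis) <- rownames(E)
  class(out) <- "principal_subspace"
  out
}

#' @export
print.principal_subspace <- function(x, ...) {
  cat("Principal embedding subspace: p =", nrow(x$basis),
      ", k =", ncol(x$basis), "\n")
  cat("Leading singular values:",
      paste(signif(utils::head(x$values, 5L), 4L), collapse = ", "),
      if (length(x$values) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Fraction of a signal captured by the leading principal axes
#'
#' The alignment of a signal vector `y` with the first `k` principal axes,
#' `||U_{1:k}' y||^2 / ||y||^2` -- the share of the signal's squared norm
#' lying in the span of the top `k` embedding singular vectors. Values near
#' 1 at small `k` indicate that the signal concentrates on the embedding
#' principal subspace.
#'
#' @param U a `"principal_subspace"` (or an orthonormal-column matrix).
#' @param y numeric signal vector of length `p`, not all zero.
#' @param k number of leading axes to use, at most `ncol` of the basis.
#' @return a scalar in `[0, 1]`.
#' @export
subspace_alignment <- function(U, y, k = NULL) {
  B <- basis_of(U)
  y <- as.numeric(y)
  if (length(y) != nrow(B)) {
    stop("length(y) must equal nrow of the basis", call. = FALSE)
  }
  ny2 <- sum(y^2)
  if (ny2 == 0) stop("`y` must be nonzero", call. = FALSE)
  if (is.null(k)) k <- ncol(B)
  k <- check_count(k, "k")
  if (k > ncol(B)) {
    stop("`k` (", k, ") exceeds the number of basis columns (",
         ncol(B), ")", call. = FALSE)
  }
  sum(crossprod(B[, seq_len(k), drop = FALSE], y)^2) / ny2
}

#' Alignment profile over every subspace dimension
#'
#' Evaluates [subspace_alignment()] for `k = 1, ..., p` against a full
#' (square, orthogonal) basis. The profile is nondecreasing and ends at 1.
#'
#' @param U a square orthogonal basis (or `"principal_subspace"` with
#'   `k = p`).
#' @inheritParams subspace_alignment
#' @return numeric vector of length `p`; entry `k` is the alignment at
#'   dimension `k`.
#' @export
alignment_profile <- function(U, y) {
  B <- basis_of(U)
  if (nrow(B) != ncol(B)) {
    stop("`U` must be a square orthogonal basis (k = p)", call. = FALSE)
  }
  y <- as.numeric(y)
  ny2 <- sum(y^2)
  if (ny2 == 0) stop("`y` must be nonzero", call. = FALSE)
  cumsum(as.numeric(crossprod(B, y))^2) / ny2
}

#' Draw a Haar-distributed random orthogonal matrix
#'
#' QR factorization of an i.i.d. standard Gaussian matrix with the sign
#' convention that the diagonal of R is positive, which makes the Q factor
#' exactly Haar-uniform on the orthogonal group (Mezzadri construction).
#'
#' @param p matrix dimension.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return a `p x p` orthogonal matrix.
#' @export
sample_haar_orthogonal <- function(p, seed = NULL) {
  p <- check_count(p, "p")
  with_seed(seed, {
    Z <- matrix(stats::rnorm(p * p), p, p)
    qz <- qr(Z)
    Q <- qr.Q(qz)
    sgn <- sign(diag(qr.R(qz)))
    sgn[sgn == 0] <- 1
    sweep(Q, 2L, sgn, "*")
  })
}

#' Null band for the alignment profile under Haar rotation
#'
#' Simulates the alignment profile of `y` against independently drawn
#' Haar-random orthogonal bases and returns pointwise empirical quantiles.
#' Under a rotation-uniform ("uninformative") basis the expected alignment
#' at dimension `k` is `k/p`; a profile escaping above the band indicates
#' that the embedding axes capture more of the signal than chance.
#'
#' @inheritParams subspace_alignment
#' @param n_reps number of Haar draws (>= 2); 100 gives the conventional
#'   display.
#' @param lower_q,upper_q band quantiles, `0 < lower_q < upper_q < 1`.
#' @param seed optional integer seed.
#' @return a list with numeric length-`p` vectors `lower` and `upper`.
#' @export
alignment_null_band <- function(y, n_reps = 100L, lower_q = 0.025,
                                upper_q = 0.975, seed = NULL) {
  y <- as.numeric(y)
  if (sum(y^2) == 0) stop("`y` must be nonzero", call. = FALSE)
  n_reps <- check_count(n_reps, "n_reps", min = 2L)
  if (!(lower_q > 0 && lower_q < upper_q && upper_q < 1)) {
    stop("require 0 < lower_q < upper_q < 1", call. = FALSE)
  }
  p <- length(y)
  profiles <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      alignment_profile(sample_haar_orthogonal(p), y)
    }, numeric(p))
  })
  # profiles is p x n_reps
  list(
    lower = apply(profiles, 1L, stats::quantile, probs = lower_q,
                  names = FALSE),
    upper = apply(profiles, 1L, stats::quantile, probs = upper_q,
                  names = FALSE)
  )
}

#' Embedding-alignment diagnostic
#'
#' Convenience wrapper computing the alignment profile of a signal against
#' the principal axes of an embedding matrix together with its Haar-random
#' null band, for a Figure-1-style diagnostic plot.
#'
#' @inheritParams reduce_embeddings
#' @param y signal vector of length `nrow(E)` (e.g. a difference of average
#'   expression profiles).
#' @param n_reps,lower_q,upper_q,seed passed to [alignment_null_band()].
#' @param standardize whether to center/scale embedding columns before the
#'   decomposition (both conventions are in use; the subspace changes only
#'   mildly for well-behaved embeddings).
#' @return an object of class `"embedding_alignment"` with fields `profile`,
#'   `lower`, `upper`.
#' @export
embedding_alignment <- function(E, y, n_reps = 100L, lower_q = 0.025,
                                upper_q = 0.975, seed = NULL,
                                standardize = TRUE) {
  E <- as_embedding_matrix(E)
  if (standardize) E <- standardize_columns(E)
  p <- nrow(E)
  sv <- svd(E, nu = min(dim(E)), nv = 0L)
  U <- fix_signs(sv$u)
  if (ncol(U) < p) {
    # complete to a square orthogonal basis so the profile reaches 1
    U <- qr.Q(qr(cbind(U, diag(p))))[, seq_len(p), drop = FALSE]
  }
  band <- alignment_null_band(y, n_reps = n_reps, lower_q = lower_q,
                              upper_q = upper_q, seed = seed)
  out <- list(profile = alignment_profile(U, y),
              lower = band$lower, upper = band$upper)
  class(out) <- "embedding_alignment"
  out
}

#' @export
print.embedding_alignment <- function(x, ...) {
  p <- length(x$profile)
  ks <- unique(pmin(p, c(1L, 5L, 10L, 50L, p)))
  cat("Embedding-alignment diagnostic (p =", p, ")\n")
  for (k in ks) {
    cat(sprintf("  k = %4d: alignment %.3f  null band [%.3f, %.3f]\n",
                k, x$profile[k], x$lower[k], x$upper[k]))
  }
  invisible(x)
}

#' @export
#' @importFrom graphics lines legend
plot.embedding_alignment <- function(x, ...) {
  p <- length(x$profile)
  plot(seq_len(p), x$profile, type = "l", col = "blue", lwd = 2,
       xlab = "subspace dimension k", ylab = expression(alpha[k]),
       ylim = c(0, 1), ...)
  lines(seq_len(p), x$lower, lty = 2)
  lines(seq_len(p), x$upper, lty = 2)
  legend("bottomright", legend = c("embedding axes", "Haar null band"),
         col = c("blue", "black"), lty = c(1, 2), bty = "n")
  invisible(x)
}

# --- internal -------------------------------------------------------------

as_embedding_matrix <- function(E) {
  E <- as.matrix(E)
  storage.mode(E) <- "double"
  if (!all(is.finite(E))) stop("embedding matrix has non-finite entries",
                               call. = FALSE)
  if (nrow(E) < 2L) stop("need at least 2 genes (rows)", call. = FALSE)
  ids <- rownames(E)
  if (!is.null(ids) && anyDuplicated(ids)) {
    stop("duplicate gene identifiers in embedding row names", call. = FALSE)
  }
  E
}

standardize_columns <- function(E) {
  sds <- apply(E, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all embedding columns are constant", call. = FALSE)
  if (!all(keep)) {
    warning(sum(!keep), " constant embedding column(s) dropped",
            call. = FALSE)
    E <- E[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  scale(E, center = TRUE, scale = sds)
}

# Deterministic sign convention: make the largest-magnitude entry of each
# column positive so singular vectors are reproducible across platforms.
fix_signs <- function(U) {
  sgn <- apply(U, 2L, function(u) {
    s <- sign(u[which.max(abs(u))])
    if (s == 0) 1 else s
  })
  sweep(U, 2L, sgn, "*")
}

basis_of <- function(U) {
  if (inherits(U, "principal_subspace")) return(U$basis)
  as.matrix(U)
}
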
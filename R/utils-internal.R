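# Internal numerical helpers shared across engines.

#' Cholesky factor with adaptive ridge
#'
#' Attempts `chol(S)` directly; if the matrix is numerically singular
#' (e.g. duplicated SNPs in perfect LD) a small ridge is added to the
#' diagonal and factorization retried. Keeping the ridge conditional means
#' well-conditioned matrices are factored exactly.
#'
#' @param S symmetric positive (semi-)definite matrix.
#' @param ridge diagonal inflation used only on factorization failure.
#' @return upper-triangular Cholesky factor `R` with `t(R) %*% R == S`.
#' @noRd
chol_safe <- function(S, ridge = 1e-6) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(chol(S + diag(ridge, nrow(S))), error = function(e) NULL)
  }
  if (is.null(out)) {
    stop("matrix is not positive definite even after ridge of ", ridge)
  }
  out
}

# log N(x; mu, Sigma) given the upper Cholesky factor of Sigma
logdmvn_chol <- function(x, mu, R) {
  m <- length(x)
  u <- forwardsolve(t(R), x - mu)
  -0.5 * (m * log(2 * pi) + sum(u^2)) - sum(log(diag(R)))
}

# one MVN draw given upper Cholesky factor (t(R) %*% z has covariance Sigma)
rmvn_chol <- function(n, mu, R) {
  m <- length(mu)
  z <- matrix(stats::rnorm(n * m), nrow = m)
  t(crossprod(R, z) + mu)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# scalar, finite, single-valued checks used by argument validation
stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
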
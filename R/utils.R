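# Internal numerical helpers shared across modules.

# Tolerance for "sums to one" checks on weights and probability rows.
.norm_tol <- 1e-9

# Switchover half-width around q = 1 for the Shannon-limit branch.
.q1_tol <- 1e-10

.is_q1 <- function(q) is.finite(q) && abs(q - 1) < .q1_tol

.check_prob_vector <- function(p, what = "p") {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    stop(sprintf("'%s' must be a numeric vector without NAs", what), call. = FALSE)
  }
  if (any(p < 0)) {
    stop(sprintf("'%s' has negative entries", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > .norm_tol) {
    stop(sprintf("'%s' must sum to 1 (off by %.3g); not renormalizing silently",
                 what, sum(p) - 1), call. = FALSE)
  }
  invisible(p)
}

.check_q <- function(q, positive = FALSE) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q)) {
    stop("'q' must be a single numeric value", call. = FALSE)
  }
  if (q < 0) stop("elasticity 'q' must be >= 0", call. = FALSE)
  if (positive && q == 0) {
    stop("undefined at q=0: the effective volume of a distribution with unbounded support diverges",
         call. = FALSE)
  }
  invisible(q)
}

# Log-determinant of a symmetric positive-definite matrix via Cholesky;
# errors when the matrix is not PD (relative eigenvalue floor 1e-12).
.logdet_pd <- function(S, what = "cov") {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(sprintf("'%s' must be a square matrix", what), call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-10 * max(1, max(abs(S)))) {
    stop(sprintf("'%s' is not symmetric", what), call. = FALSE)
  }
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    stop(sprintf("'%s' is not positive definite", what), call. = FALSE)
  }
  d <- diag(R)
  # guard against numerically singular factors that chol() let through
  if (min(d)^2 <= 1e-12 * max(d)^2) {
    stop(sprintf("'%s' is numerically singular (eigenvalue ratio below 1e-12)", what),
         call. = FALSE)
  }
  2 * sum(log(d))
}

# Multivariate normal log-density at the columns of x (n x m), via Cholesky.
.mvn_logpdf <- function(x, mean, cov) {
  n <- length(mean)
  x <- matrix(x, nrow = n)
  R <- chol(cov)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

# Stable log(sum(exp(lx))) down columns of a matrix.
.logsumexp <- function(lx) {
  m <- apply(lx, 2, max)
  finite <- is.finite(m)
  out <- m
  out[finite] <- m[finite] +
    log(colSums(exp(sweep(lx[, finite, drop = FALSE], 2, m[finite]))))
  out[!finite] <- -Inf
  out
}
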
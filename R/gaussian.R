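#' Gaussian component and Gaussian mixture constructors
#'
#' A Gaussian mixture is a weighted set of n-dimensional Gaussian components
#' sharing a common dimension. Covariances must be symmetric and positive
#' definite (smallest/largest eigenvalue ratio above 1e-12), since both the
#' density and the effective-volume formula require a finite log-determinant.
#'
#' @param mean numeric mean vector (a scalar gives a univariate component).
#' @param cov covariance matrix; a scalar or length-n vector is taken as a
#'   diagonal (co)variance.
#' @return `gaussian_component()` returns an object of class
#'   `gaussian_component` with elements `mean`, `cov` and the dimension `n`.
#' @examples
#' gc <- gaussian_component(0, 0.25) # univariate, sd 0.5
#' gaussian_renyi(gc, q = 1)
#' @export
gaussian_component <- function(mean, cov) {
  mean <- as.numeric(mean)
  n <- length(mean)
  if (!is.matrix(cov)) {
    if (length(cov) == 1L) cov <- diag(rep(as.numeric(cov), n), n)
    else if (length(cov) == n) cov <- diag(as.numeric(cov), n)
    else stop("'cov' must be an n x n matrix, a scalar, or a length-n diagonal",
              call. = FALSE)
  }
  if (nrow(cov) != n) stop("dimension mismatch between 'mean' and 'cov'",
                           call. = FALSE)
  .logdet_pd(cov, "cov") # validates symmetry + positive definiteness
  structure(list(mean = mean, cov = unname(cov), n = n),
            class = "gaussian_component")
}

#' @param components list of `gaussian_component` objects sharing a dimension.
#' @param weights component proportions in \[0, 1\] summing to 1
#'   (tolerance 1e-9).
#' @return `gaussian_mixture()` returns an object of class `gaussian_mixture`
#'   with elements `components`, `weights` and `n`.
#' @rdname gaussian_component
#' @examples
#' mix <- gaussian_mixture(
#'   list(gaussian_component(0, 0.25), gaussian_component(6, 0.25)),
#'   weights = c(0.5, 0.5)
#' )
#' @export
gaussian_mixture <- function(components, weights) {
  if (inherits(components, "gaussian_component")) components <- list(components)
  if (!length(components) || !all(vapply(components, inherits, logical(1),
                                         "gaussian_component"))) {
    stop("'components' must be a non-empty list of gaussian_component objects",
         call. = FALSE)
  }
  dims <- vapply(components, `[[`, integer(1), "n")
  if (length(unique(dims)) != 1L) {
    stop("all components must share the same dimension", call. = FALSE)
  }
  if (length(weights) != length(components)) {
    stop("length(weights) must equal the number of components", call. = FALSE)
  }
  .check_prob_vector(weights, "weights")
  structure(list(components = components, weights = as.numeric(weights),
                 n = dims[1]),
            class = "gaussian_mixture")
}

#' Convenience constructor for univariate Gaussian mixtures
#'
#' @param means,sds numeric vectors of component means and standard deviations.
#' @param weights component proportions; default equal.
#' @return A univariate `gaussian_mixture`.
#' @export
gaussian_mixture_1d <- function(means, sds, weights = NULL) {
  N <- length(means)
  sds <- rep_len(sds, N)
  if (is.null(weights)) weights <- rep(1 / N, N)
  gaussian_mixture(
    lapply(seq_len(N), function(i) gaussian_component(means[i], sds[i]^2)),
    weights
  )
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d components in %d dimension(s)\n",
              length(x$components), x$n))
  invisible(x)
}

#' Rényi heterogeneity (effective volume) of a multivariate Gaussian
#'
#' Closed form for the effective volume of support of an n-dimensional
#' Gaussian:
#' \deqn{\Pi_q = (2\pi)^{n/2} q^{n/(2(q-1))} |\Sigma|^{1/2}, \quad
#'       q \notin \{0, 1, \infty\},}
#' with limits \eqn{(2\pi e)^{n/2}|\Sigma|^{1/2}} at q = 1 and
#' \eqn{(2\pi)^{n/2}|\Sigma|^{1/2}} at q = Inf. The value is the side-length
#' product of the n-cube carrying a uniform density with the same Rényi
#' heterogeneity. Undefined at q = 0 (a Gaussian's support is unbounded), so
#' q = 0 is rejected. The determinant is accumulated in log space from a
#' Cholesky factor.
#'
#' @param comp a [gaussian_component()].
#' @param q elasticity; `q > 0` or `Inf`.
#' @return Effective volume (numbers-equivalent scalar).
#' @examples
#' gaussian_renyi(gaussian_component(0, 0.25), q = 1) # ~2.07
#' @export
gaussian_renyi <- function(comp, q) {
  stopifnot(inherits(comp, "gaussian_component"))
  .check_q(q, positive = TRUE)
  n <- comp$n
  ld <- .logdet_pd(comp$cov)
  if (is.infinite(q)) return(exp(n / 2 * log(2 * pi) + ld / 2))
  if (.is_q1(q)) return(exp(n / 2 * (log(2 * pi) + 1) + ld / 2))
  exp(n / 2 * log(2 * pi) + n * log(q) / (2 * (q - 1)) + ld / 2)
}

# log of the integral of the q-th power of a Gaussian density:
# integral f^q dx = (2 pi)^{n(1-q)/2} q^{-n/2} |Sigma|^{(1-q)/2}, q > 0 finite.
.log_int_gauss_pow <- function(comp, q) {
  n <- comp$n
  ld <- .logdet_pd(comp$cov)
  (1 - q) * (n / 2) * log(2 * pi) - (n / 2) * log(q) + (1 - q) * ld / 2
}

#' Within-component (alpha) heterogeneity of a Gaussian mixture
#'
#' Closed-form effective volume per mixture component: the continuous
#' analogue of the Jost alpha, using the q-normalized weights
#' \eqn{\tilde w_i = w_i^q/\sum_k w_k^q}. At q = 1 it equals
#' \eqn{\exp\{\frac12 [n + \sum_i w_i \log((2\pi)^n |\Sigma_i|)]\}}, the
#' exponential of the weighted mean differential entropy; at q = Inf it is 0;
#' q = 0 is undefined and rejected. A single-component mixture reproduces
#' [gaussian_renyi()] at every admissible q. Note alpha does not depend on
#' the component means.
#'
#' @param mix a [gaussian_mixture()].
#' @param q elasticity; `q > 0` or `Inf`.
#' @return Effective volume per component (0 at q = Inf).
#' @export
gaussian_mixture_alpha <- function(mix, q) {
  stopifnot(inherits(mix, "gaussian_mixture"))
  .check_q(q, positive = TRUE)
  if (is.infinite(q)) return(0)
  keep <- mix$weights > 0
  w <- mix$weights[keep]
  comps <- mix$components[keep]
  n <- mix$n
  if (.is_q1(q)) {
    lds <- vapply(comps, function(cc) .logdet_pd(cc$cov), numeric(1))
    return(exp(0.5 * (n + sum(w * (n * log(2 * pi) + lds)))))
  }
  lw <- q * log(w) - .logsumexp(matrix(q * log(w), ncol = 1))
  li <- vapply(comps, .log_int_gauss_pow, numeric(1), q = q)
  log_sum <- .logsumexp(matrix(lw + li, ncol = 1))
  exp(log_sum / (1 - q))
}

#' Parametric (moment-matched) pooling of a Gaussian mixture
#'
#' Pools a Gaussian mixture into a single Gaussian with the mixture's first
#' two moments: \eqn{\mu^* = \sum_i w_i \mu_i} and
#' \eqn{\Sigma^* = -\mu^*{\mu^*}^T + \sum_i w_i(\Sigma_i + \mu_i\mu_i^T)}.
#' This is the pooling implicit in Gaussian mixed-effects (random-effects
#' meta-analysis) models. \eqn{\Sigma^*} is symmetrized after assembly to
#' absorb floating-point asymmetry; it always dominates the average
#' within-component covariance, the difference being the covariance of the
#' component means.
#'
#' @param mix a [gaussian_mixture()].
#' @return A `gaussian_component` (subclass `pooled_gaussian`) with the pooled
#'   mean and covariance.
#' @export
pool_parametric <- function(mix) {
  stopifnot(inherits(mix, "gaussian_mixture"))
  n <- mix$n
  mu_star <- rep(0, n)
  for (i in seq_along(mix$weights)) {
    mu_star <- mu_star + mix$weights[i] * mix$components[[i]]$mean
  }
  S <- -tcrossprod(mu_star)
  for (i in seq_along(mix$weights)) {
    ci <- mix$components[[i]]
    S <- S + mix$weights[i] * (ci$cov + tcrossprod(ci$mean))
  }
  S <- (S + t(S)) / 2
  out <- gaussian_component(mu_star, S)
  class(out) <- c("pooled_gaussian", class(out))
  out
}

#' Closed-form decomposition of a parametric Gaussian mixture
#'
#' gamma is the effective volume of the moment-matched pooled Gaussian
#' ([pool_parametric()]), alpha the closed-form within-component volume
#' ([gaussian_mixture_alpha()]), and beta = gamma / alpha. At q = 1, beta is
#' guaranteed to be at least 1; at q != 1 the bound can fail (for instance
#' when narrow components carry the most weight), so beta is reported
#' unclamped and flagged via `beta_below_one`.
#'
#' @inheritParams gaussian_mixture_alpha
#' @return A `renyi_decomposition` with `pooling = "parametric"`.
#' @examples
#' mix <- gaussian_mixture_1d(c(-2, 2), sds = 1)
#' parametric_decompose(mix, q = 1)
#' @export
parametric_decompose <- function(mix, q) {
  stopifnot(inherits(mix, "gaussian_mixture"))
  .check_q(q, positive = TRUE)
  if (is.infinite(q)) {
    stop("beta undefined: alpha is 0 at q=Inf", call. = FALSE)
  }
  gamma <- gaussian_renyi(pool_parametric(mix), q)
  alpha <- gaussian_mixture_alpha(mix, q)
  new_decomposition(q = q, gamma = gamma, alpha = alpha, beta = gamma / alpha,
                    pooling = "parametric", method = "closed_form")
}

#' Weighted-determinant inequality check
#'
#' Tests the log-determinant inequality
#' \eqn{|\sum_i w_i \Sigma_i|^{1/2} \ge \prod_i |\Sigma_i|^{w_i/2}}
#' for a set of symmetric positive (semi)definite matrices with proportions
#' `w`. This inequality underlies the q = 1 lower bound beta >= 1 of the
#' parametric decomposition; the check is evaluated in log space with
#' tolerance 1e-9 and is expected to hold on every valid input.
#'
#' @param covs list of symmetric PSD matrices of a common dimension (N >= 2).
#' @param weights proportions summing to 1.
#' @return `TRUE` if the inequality holds (within tolerance), else `FALSE`.
#' @export
check_lemma2 <- function(covs, weights) {
  if (length(covs) < 2L) stop("need at least two matrices", call. = FALSE)
  dims <- vapply(covs, nrow, integer(1))
  if (length(unique(dims)) != 1L ||
      any(vapply(covs, ncol, integer(1)) != dims[1])) {
    stop("all matrices must be square with a common dimension", call. = FALSE)
  }
  .check_prob_vector(weights, "weights")
  Sbar <- Reduce(`+`, Map(`*`, covs, weights))
  # determinant() handles the PSD (possibly singular) case: log det -> -Inf
  lhs <- 0.5 * as.numeric(determinant(Sbar, logarithm = TRUE)$modulus)
  rhs <- 0.5 * sum(weights * vapply(covs, function(S) {
    as.numeric(determinant(S, logarithm = TRUE)$modulus)
  }, numeric(1)))
  if (!is.finite(rhs)) return(TRUE) # some |Sigma_i| = 0: right side is 0
  lhs >= rhs - 1e-9
}

#' Scale the component means of a Gaussian mixture
#'
#' Returns a mixture with means `c * mu_i` and unchanged weights and
#' covariances. For `c >= 1` the parametric pooled-mixture heterogeneity is
#' non-decreasing in `c` (spreading component locations can only inflate the
#' pooled covariance), which this helper exists to exercise; `c < 1` is
#' rejected.
#'
#' @param mix a [gaussian_mixture()].
#' @param c scale factor, `c >= 1`.
#' @return A `gaussian_mixture` with scaled means.
#' @export
scale_means <- function(mix, c) {
  stopifnot(inherits(mix, "gaussian_mixture"))
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 1) {
    stop("'c' must be a single numeric >= 1", call. = FALSE)
  }
  comps <- lapply(mix$components, function(cc) {
    gaussian_component(c * cc$mean, cc$cov)
  })
  gaussian_mixture(comps, mix$weights)
}
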
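#' Discrete mixture of categorical distributions
#'
#' A discrete mixture is a system pooled from N component subsystems, each a
#' categorical distribution over the same n states, with component proportions
#' `weights`. The pooled distribution is the weighted average
#' \eqn{\bar p = P^T w} of the component rows.
#'
#' @param weights numeric vector of N component proportions in \[0, 1\],
#'   summing to 1 (tolerance 1e-9; no silent renormalization).
#' @param distributions N x n matrix whose i-th row is the state distribution
#'   of component i; rows must be non-negative and sum to 1.
#'
#' @return An object of class `discrete_mixture` with elements `weights`,
#'   `distributions` and the derived `pooled` distribution.
#' @examples
#' mix <- discrete_mixture(c(0.5, 0.5), rbind(c(1, 0), c(0, 1)))
#' discrete_decompose(mix, q = 1)
#' @export
discrete_mixture <- function(weights, distributions) {
  if (is.vector(distributions)) distributions <- matrix(distributions, nrow = 1)
  distributions <- as.matrix(distributions)
  if (length(weights) != nrow(distributions)) {
    stop("length(weights) must equal nrow(distributions)", call. = FALSE)
  }
  .check_prob_vector(weights, "weights")
  for (i in seq_len(nrow(distributions))) {
    .check_prob_vector(distributions[i, ], sprintf("distributions[%d, ]", i))
  }
  structure(
    list(weights = as.numeric(weights),
         distributions = unname(distributions),
         pooled = as.numeric(crossprod(distributions, weights))),
    class = "discrete_mixture"
  )
}

#' @export
print.discrete_mixture <- function(x, ...) {
  cat(sprintf("Discrete mixture: %d components over %d states\n",
              length(x$weights), ncol(x$distributions)))
  invisible(x)
}

#' Rényi heterogeneity of a discrete distribution (Hill number)
#'
#' Computes the effective number of states
#' \eqn{(\sum_j p_j^q)^{1/(1-q)}}, known as the Hill number of order q in
#' ecology and the Hannah-Kay index in economics. At q = 1 the Shannon limit
#' \eqn{\exp(-\sum_j p_j \log p_j)} is used, at q = 0 it is the richness
#' (number of states with positive probability), and at q = Inf the Berger-
#' Parker dominance limit \eqn{1/\max_j p_j}. Zero-probability states never
#' contribute: `0 * log(0)` is taken as 0 and zeros are excluded from the
#' q = 0 count.
#'
#' @param p probability vector (validated, not renormalized).
#' @param q elasticity, `q >= 0`; controls sensitivity to rare states.
#' @return Effective number of states (a scalar `>= 1`).
#' @examples
#' hill_number(rep(1 / 4, 4), q = 2) # 4: uniform over 4 states
#' hill_number(c(0.5, 0.25, 0.25), q = 2) # 1 / 0.375
#' @export
hill_number <- function(p, q) {
  .check_prob_vector(p, "p")
  .check_q(q)
  p <- p[p > 0]
  if (q == 0) return(as.numeric(length(p)))
  if (is.infinite(q)) return(1 / max(p))
  if (.is_q1(q)) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Within-component (alpha) heterogeneity of a discrete mixture
#'
#' The Jost alpha component: the effective number of states per component,
#' computed with the q-dependent weight normalization
#' \eqn{\tilde w_i = w_i^q / \sum_k w_k^q} so that gamma = alpha x beta holds
#' multiplicatively. At q = 1 it is \eqn{\exp} of the weighted mean of the
#' component Shannon entropies. Components with zero weight are dropped
#' before evaluation: an absent component contributes nothing at any q.
#'
#' @inheritParams discrete_decompose
#' @return Effective number of states per component.
#' @export
discrete_alpha <- function(mix, q) {
  stopifnot(inherits(mix, "discrete_mixture"))
  .check_q(q)
  keep <- mix$weights > 0
  w <- mix$weights[keep]
  P <- mix$distributions[keep, , drop = FALSE]
  if (.is_q1(q)) {
    ent <- vapply(seq_along(w), function(i) {
      p <- P[i, ]
      p <- p[p > 0]
      -sum(p * log(p))
    }, numeric(1))
    return(exp(sum(w * ent)))
  }
  if (is.infinite(q)) {
    # q -> Inf limit of Eq-5-style average: dominated by the largest
    # within-component probability under the heaviest weight
    return(1 / max(vapply(seq_along(w), function(i) max(P[i, ]), numeric(1))[
      w == max(w)]))
  }
  wt <- w^q / sum(w^q)
  inner <- vapply(seq_along(w), function(i) {
    p <- P[i, ]
    sum(p[p > 0]^q)
  }, numeric(1))
  sum(wt * inner)^(1 / (1 - q))
}

#' Multiplicative alpha/beta/gamma decomposition of a discrete mixture
#'
#' Decomposes the pooled-system heterogeneity as gamma = alpha x beta:
#' gamma is the Hill number of the pooled distribution \eqn{\bar p = P^T w},
#' alpha the within-component heterogeneity ([discrete_alpha()]), and
#' beta = gamma / alpha the effective number of distinct components.
#'
#' @param mix a [discrete_mixture()].
#' @param q elasticity, `q >= 0`.
#' @return A `renyi_decomposition` with `pooling = "discrete"`.
#' @examples
#' mix <- discrete_mixture(c(0.5, 0.5), rbind(c(1, 0), c(0, 1)))
#' discrete_decompose(mix, q = 1) # two disjoint components: beta = 2
#' @export
discrete_decompose <- function(mix, q) {
  stopifnot(inherits(mix, "discrete_mixture"))
  .check_q(q)
  gamma <- hill_number(mix$pooled, q)
  alpha <- discrete_alpha(mix, q)
  new_decomposition(q = q, gamma = gamma, alpha = alpha, beta = gamma / alpha,
                    pooling = "discrete", method = "closed_form")
}
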
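#' Heterogeneity decomposition record
#'
#' Container returned by [discrete_decompose()], [parametric_decompose()] and
#' [nonparametric_decompose()]. Holds the elasticity together with the gamma
#' (pooled), alpha (within-component) and beta (between-component,
#' \eqn{\beta = \gamma/\alpha}) heterogeneity, all expressed in numbers
#' equivalent, plus estimator metadata.
#'
#' @param q elasticity at which the decomposition was evaluated.
#' @param gamma,alpha,beta effective sizes; `beta` is the effective number of
#'   distinct components.
#' @param pooling one of `"discrete"`, `"nonparametric"`, `"parametric"`.
#' @param method one of `"closed_form"`, `"quadrature"`, `"monte_carlo"`,
#'   `"asymptotic"`.
#' @param error_estimate absolute error bound (quadrature) or standard error
#'   (Monte Carlo) of `gamma`, or `NA` for exact methods.
#' @param n_samples,seed Monte Carlo sample count and seed, or `NA`.
#'
#' @return An object of class `renyi_decomposition`: a list with the above
#'   fields plus `beta_below_one`, a flag marking decompositions where the
#'   between-component heterogeneity fell below 1 (possible under parametric
#'   pooling at elasticities other than 1; never clamped).
#' @keywords internal
new_decomposition <- function(q, gamma, alpha, beta, pooling, method,
                              error_estimate = NA_real_,
                              n_samples = NA_integer_, seed = NA_integer_) {
  pooling <- match.arg(pooling, c("discrete", "nonparametric", "parametric"))
  method <- match.arg(method, c("closed_form", "quadrature", "monte_carlo",
                                "asymptotic"))
  structure(
    list(q = q, gamma = gamma, alpha = alpha, beta = beta,
         pooling = pooling, method = method,
         error_estimate = error_estimate,
         n_samples = n_samples, seed = seed,
         beta_below_one = is.finite(beta) && beta < 1),
    class = "renyi_decomposition"
  )
}

#' @export
print.renyi_decomposition <- function(x, ...) {
  cat(sprintf("Renyi heterogeneity decomposition (q = %g, %s pooling, %s)\n",
              x$q, x$pooling, x$method))
  cat(sprintf("  gamma = %.6g\n  alpha = %.6g\n  beta  = %.6g%s\n",
              x$gamma, x$alpha, x$beta,
              if (isTRUE(x$beta_below_one)) "   [beta < 1]" else ""))
  if (is.finite(x$error_estimate)) {
    cat(sprintf("  gamma error estimate: %.3g\n", x$error_estimate))
  }
  if (!is.na(x$n_samples)) {
    cat(sprintf("  samples: %d (seed %d)\n", x$n_samples, x$seed))
  }
  invisible(x)
}

#' @export
as.data.frame.renyi_decomposition <- function(x, ...) {
  data.frame(q = x$q, gamma = x$gamma, alpha = x$alpha, beta = x$beta,
             pooling = x$pooling, method = x$method,
             error_estimate = x$error_estimate,
             n_samples = x$n_samples, seed = x$seed,
             beta_below_one = x$beta_below_one,
             stringsAsFactors = FALSE)
}
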
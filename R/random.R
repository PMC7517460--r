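#' Randomized Gaussian mixtures for property sweeps
#'
#' Draws a random Gaussian mixture for stress-testing the decomposition
#' bounds: weights from a flat Dirichlet (or exactly equal), means i.i.d.
#' normal with spread `mean_scale`, and covariances built as
#' \eqn{A A^T + 0.1 I} from a square Gaussian matrix A, which keeps them
#' comfortably positive definite across dimensions.
#'
#' @param n_dim dimension of the component Gaussians.
#' @param n_comp number of components.
#' @param equal_weights if `TRUE`, weights are `1/n_comp` each.
#' @param mean_scale standard deviation of the random component means.
#' @return A [gaussian_mixture()].
#' @examples
#' set.seed(7)
#' mix <- random_gaussian_mixture(n_dim = 2, n_comp = 3)
#' parametric_decompose(mix, q = 1)$beta >= 1
#' @export
random_gaussian_mixture <- function(n_dim = 1L, n_comp = 2L,
                                    equal_weights = FALSE, mean_scale = 3) {
  stopifnot(n_dim >= 1L, n_comp >= 1L)
  w <- if (equal_weights) {
    rep(1 / n_comp, n_comp)
  } else {
    g <- stats::rgamma(n_comp, shape = 1)
    g / sum(g)
  }
  comps <- lapply(seq_len(n_comp), function(i) {
    A <- matrix(stats::rnorm(n_dim * n_dim), n_dim)
    gaussian_component(stats::rnorm(n_dim, sd = mean_scale),
                       tcrossprod(A) + diag(0.1, n_dim))
  })
  gaussian_mixture(comps, w)
}
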
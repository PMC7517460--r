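#' Geometric weight-skew family
#'
#' Generates a weight vector whose entries grow (a > 1) or shrink (a < 1)
#' geometrically across components: \eqn{w_i(a) \propto a^{(i-1)/(N-1)}},
#' normalized to sum to 1, with the limit branches w(0) = (1, 0, ..., 0),
#' w(1) = uniform, and w(Inf) = (0, ..., 0, 1) taken exactly. With N = 4 this
#' is \eqn{w_i(a) = a^{(i-1)/3} (a^{1/3} - 1) / (a^{4/3} - 1)}. Used to
#' anti-correlate (a < 1) or correlate (a > 1) component weights with
#' component spreads when probing where beta >= 1 can fail under parametric
#' pooling at q != 1.
#'
#' @param a skew parameter, `a >= 0` (including `Inf`).
#' @param N number of components, `N >= 2`.
#' @return Weight vector of length N summing to 1 (within 1e-12).
#' @examples
#' skew_weights(1, 4) # uniform
#' skew_weights(2, 4) # ratio w_4 / w_1 = 2
#' @export
skew_weights <- function(a, N = 4L) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0) {
    stop("'a' must be a single numeric >= 0", call. = FALSE)
  }
  N <- as.integer(N)
  if (N < 2L) stop("'N' must be at least 2", call. = FALSE)
  if (a == 0) return(c(1, rep(0, N - 1)))
  if (a == 1) return(rep(1 / N, N))
  if (is.infinite(a)) return(c(rep(0, N - 1), 1))
  w <- a^((seq_len(N) - 1) / (N - 1))
  w / sum(w)
}

# Equally spaced component means spanning [0, separation].
.spaced_means <- function(N, separation) {
  if (N == 1L) return(0)
  seq(0, separation, length.out = N)
}

#' Separation sweep for equally weighted univariate mixtures
#'
#' Builds equally weighted univariate Gaussian mixtures with common standard
#' deviation `sd` and component means equally spaced across each requested
#' max-min separation, then decomposes each non-parametrically with the
#' quadrature estimator. alpha is constant across rows (it is independent of
#' the means), while beta climbs from 1 (coincident components) and saturates
#' at N once components stop overlapping.
#'
#' @param separations max-min distances between component means.
#' @param N_list component counts to sweep.
#' @param sd common component standard deviation.
#' @param q elasticity.
#' @param rel_tol quadrature tolerance.
#' @return A data.frame with columns `N`, `separation`, `q`, `gamma`, `alpha`,
#'   `beta`, `error_estimate`.
#' @examples
#' run_example_separation(separations = c(0, 6), N_list = 2)
#' @export
run_example_separation <- function(separations = c(0, 2, 4, 6),
                                   N_list = c(2, 3, 4),
                                   sd = 0.5, q = 1, rel_tol = 1e-8) {
  rows <- list()
  for (N in N_list) for (s in separations) {
    mix <- gaussian_mixture_1d(.spaced_means(N, s), sds = sd)
    d <- nonparametric_decompose(mix, q, method = "quadrature",
                                 rel_tol = rel_tol)
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, separation = s, q = q, gamma = d$gamma, alpha = d$alpha,
      beta = d$beta, error_estimate = d$error_estimate)
  }
  do.call(rbind, rows)
}

#' Weight-skew sweep for a parametric mixture of unequal spreads
#'
#' Decomposes a four-component univariate parametric Gaussian mixture with
#' component standard deviations `sds` under the weight-skew family
#' ([skew_weights()]), across a grid of elasticities. Component means are all
#' 0: alpha is mean-independent and coincident means give the smallest pooled
#' variance, so any beta < 1 found here is conservative. Rows with beta < 1
#' are flagged: with spreads listed narrowest-first, the bound fails at some
#' q < 1 when a < 1 (narrow components weighted heaviest) and at some q > 1
#' when a > 1 (wide components weighted heaviest); at q = 1 beta >= 1 always.
#'
#' @param a_values skew parameters to sweep.
#' @param q_grid elasticities (> 0, finite).
#' @param sds component standard deviations.
#' @return A data.frame with columns `a`, `q`, `gamma`, `alpha`, `beta`,
#'   `beta_below_one`.
#' @examples
#' tab <- run_example_skew(a_values = c(0.32, 1), q_grid = c(1, 2))
#' subset(tab, beta_below_one)
#' @export
run_example_skew <- function(a_values = c(0.32, 0.5, 0.79, 1, 1.26, 2, 3.16),
                             q_grid = c(0.5, 1, 2, 4),
                             sds = c(0.5, 0.8, 1.1, 1.6)) {
  rows <- list()
  for (a in a_values) {
    w <- skew_weights(a, length(sds))
    mix <- gaussian_mixture_1d(rep(0, length(sds)), sds = sds, weights = w)
    for (q in q_grid) {
      d <- parametric_decompose(mix, q)
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, q = q, gamma = d$gamma, alpha = d$alpha, beta = d$beta,
        beta_below_one = d$beta_below_one)
    }
  }
  do.call(rbind, rows)
}

#' Parametric versus non-parametric beta as components separate
#'
#' For equally weighted unit-variance univariate mixtures with the mean of
#' component i at `i * mu_o`, computes beta under parametric pooling (closed
#' form) and non-parametric pooling (quadrature and the asymptotic
#' approximation) across a grid of `mu_o`. The non-parametric beta saturates
#' at the component count N, while the parametric beta keeps growing —
#' asymptotically at a constant rate in `mu_o` — because the pooled Gaussian
#' spans the gaps between components.
#'
#' @param mu_o_grid location-scale grid (>= 0).
#' @param N_list component counts.
#' @param q elasticity.
#' @param rel_tol quadrature tolerance.
#' @return A data.frame with columns `N`, `mu_o`, `q`, `beta_parametric`,
#'   `beta_nonparametric_quadrature`, `beta_nonparametric_asymptotic`.
#' @examples
#' run_separation_contrast(mu_o_grid = c(0, 10), N_list = 2)
#' @export
run_separation_contrast <- function(mu_o_grid = seq(0, 10, by = 2),
                                    N_list = c(2, 3, 4),
                                    q = 1, rel_tol = 1e-8) {
  rows <- list()
  for (N in N_list) for (mu_o in mu_o_grid) {
    mix <- gaussian_mixture_1d(seq_len(N) * mu_o, sds = 1)
    dp <- parametric_decompose(mix, q)
    dq <- nonparametric_decompose(mix, q, method = "quadrature",
                                  rel_tol = rel_tol)
    da <- nonparametric_decompose(mix, q, method = "asymptotic")
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, mu_o = mu_o, q = q,
      beta_parametric = dp$beta,
      beta_nonparametric_quadrature = dq$beta,
      beta_nonparametric_asymptotic = da$beta)
  }
  do.call(rbind, rows)
}

#' Write a sweep table as a diff-stable CSV
#'
#' Fixed column order and 12 significant digits, so regenerated sweeps diff
#' cleanly against stored fixtures.
#'
#' @param table a sweep data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], signif, digits = 12)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
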
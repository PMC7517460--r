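test_that("gaussian_renyi matches the closed-form effective volumes", {
  expect_equal(gaussian_renyi(gaussian_component(0, 0.25), 1),
               sqrt(2 * pi * exp(1)) * 0.5, tolerance = 1e-12)
  expect_equal(gaussian_renyi(gaussian_component(3, 1), Inf), sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_renyi(gaussian_component(c(0, 0), diag(2)), 1),
               2 * pi * exp(1), tolerance = 1e-12)
  # q = 2 of a standard normal: (2 pi)^(1/2) * 2^(1/2) = 2 sqrt(pi)
  expect_equal(gaussian_renyi(gaussian_component(0, 1), 2), 2 * sqrt(pi),
               tolerance = 1e-12)
})

test_that("gaussian_renyi rejects q = 0 and bad covariances", {
  expect_error(gaussian_renyi(gaussian_component(0, 1), 0), "q=0")
  expect_error(gaussian_component(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(gaussian_component(c(0, 0), matrix(c(1, 0.5, 0.2, 1), 2)),
               "symmetric")
  expect_error(gaussian_component(c(0, 0), diag(c(1, 0))), "positive definite")
})

test_that("gaussian_renyi limit branches agree with the general branch", {
  set.seed(51)
  for (rep in 1:8) {
    n <- sample(1:3, 1)
    A <- matrix(rnorm(n * n), n)
    comp <- gaussian_component(rnorm(n), tcrossprod(A) + diag(0.2, n))
    expect_equal(gaussian_renyi(comp, 1 + 1e-6), gaussian_renyi(comp, 1),
                 tolerance = 1e-4)
    expect_equal(gaussian_renyi(comp, 1 - 1e-6), gaussian_renyi(comp, 1),
                 tolerance = 1e-4)
    expect_equal(gaussian_renyi(comp, 1e6), gaussian_renyi(comp, Inf),
                 tolerance = 1e-4)
  }
})

test_that("gaussian_renyi is non-increasing in q and scales with |det A|", {
  set.seed(52)
  qs <- c(0.25, 0.5, 1, 2, 8, 100, Inf)
  for (rep in 1:8) {
    n <- sample(1:3, 1)
    B <- matrix(rnorm(n * n), n)
    comp <- gaussian_component(rnorm(n), tcrossprod(B) + diag(0.2, n))
    vals <- vapply(qs, function(q) gaussian_renyi(comp, q), numeric(1))
    expect_true(all(diff(vals) <= 1e-9 * vals[-length(vals)]))
    # invertible linear map: volume scales by |det A|
    A <- matrix(rnorm(n * n), n) + diag(2, n)
    tcomp <- gaussian_component(A %*% comp$mean,
                                A %*% comp$cov %*% t(A))
    for (q in qs) {
      expect_equal(gaussian_renyi(tcomp, q),
                   abs(det(A)) * gaussian_renyi(comp, q), tolerance = 1e-9)
    }
  }
})

test_that("mixture alpha reproduces the single-component closed form", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(1:3, 1)
    A <- matrix(rnorm(n * n), n)
    comp <- gaussian_component(rnorm(n), tcrossprod(A) + diag(0.2, n))
    mix1 <- gaussian_mixture(list(comp), 1)
    for (q in c(0.25, 0.5, 1, 2, 5)) {
      expect_equal(gaussian_mixture_alpha(mix1, q), gaussian_renyi(comp, q),
                   tolerance = 1e-12)
    }
  }
  # equally weighted sd-0.5 components: alpha is the common per-component volume
  for (N in 2:4) {
    mix <- gaussian_mixture_1d(seq_len(N), sds = 0.5)
    expect_equal(gaussian_mixture_alpha(mix, 1), sqrt(2 * pi * exp(1)) * 0.5,
                 tolerance = 1e-12)
  }
  # dominance limit: alpha of any mixture is 0 at q = Inf
  expect_identical(gaussian_mixture_alpha(gaussian_mixture_1d(c(0, 3), 1), Inf), 0)
  expect_error(gaussian_mixture_alpha(gaussian_mixture_1d(c(0, 3), 1), 0), "q=0")
})

test_that("mixture alpha agrees with numerical integration of its defining integral", {
  set.seed(54)
  sds <- c(0.5, 0.8, 1.1, 1.6)
  for (a in c(0.32, 1, 3.16)) {
    w <- skew_weights(a, 4)
    mix <- gaussian_mixture_1d(rep(0, 4), sds = sds, weights = w)
    for (q in c(0.25, 0.5, 2, 4)) {
      wt <- w^q / sum(w^q)
      ints <- vapply(sds, function(s) {
        stats::integrate(function(x) stats::dnorm(x, 0, s)^q,
                         -Inf, Inf)$value
      }, numeric(1))
      expect_equal(gaussian_mixture_alpha(mix, q), sum(wt * ints)^(1 / (1 - q)),
                   tolerance = 1e-7)
    }
  }
})

test_that("parametric pooling matches the moment-matched Gaussian", {
  # identical zero-mean components pool to themselves
  mix <- gaussian_mixture(list(gaussian_component(c(0, 0), diag(2)),
                               gaussian_component(c(0, 0), diag(2))),
                          c(0.5, 0.5))
  pooled <- pool_parametric(mix)
  expect_equal(pooled$mean, c(0, 0))
  expect_equal(pooled$cov, diag(2))
  # univariate means +/- m: pooled variance sigma^2 + m^2
  m <- 1.7; s2 <- 0.49
  mix2 <- gaussian_mixture_1d(c(-m, m), sds = sqrt(s2))
  pooled2 <- pool_parametric(mix2)
  expect_equal(pooled2$mean, 0)
  expect_equal(pooled2$cov[1, 1], s2 + m^2, tolerance = 1e-12)
  # single component pools to itself
  comp <- gaussian_component(c(1, 2), matrix(c(2, 0.3, 0.3, 1), 2))
  pooled3 <- pool_parametric(gaussian_mixture(list(comp), 1))
  expect_equal(pooled3$mean, comp$mean)
  expect_equal(pooled3$cov, comp$cov, tolerance = 1e-12)
  # pooled covariance dominates the average within-component covariance
  set.seed(55)
  for (rep in 1:10) {
    mixr <- random_gaussian_mixture(n_dim = 3, n_comp = 4)
    avg <- Reduce(`+`, Map(function(cc, w) w * cc$cov,
                           mixr$components, as.list(mixr$weights)))
    eigs <- eigen(pool_parametric(mixr)$cov - avg, symmetric = TRUE,
                  only.values = TRUE)$values
    expect_true(all(eigs >= -1e-9))
  }
})

test_that("parametric beta is at least 1 at q = 1 and flags dips elsewhere", {
  # identical components: beta exactly 1
  mix_same <- gaussian_mixture_1d(c(2, 2, 2), sds = 0.7)
  expect_equal(parametric_decompose(mix_same, 1)$beta, 1, tolerance = 1e-12)
  set.seed(56)
  for (rep in 1:100) {
    mix <- random_gaussian_mixture(n_dim = sample(1:4, 1),
                                   n_comp = sample(2:6, 1))
    d <- parametric_decompose(mix, 1)
    expect_gte(d$beta, 1 - 1e-9)
    expect_false(d$beta_below_one)
  }
  # wide components weighted heaviest: the bound fails at large q
  mix_skew <- gaussian_mixture_1d(rep(0, 4), sds = c(0.5, 0.8, 1.1, 1.6),
                                  weights = skew_weights(3.16, 4))
  d4 <- parametric_decompose(mix_skew, 4)
  expect_lt(d4$beta, 1)
  expect_true(d4$beta_below_one)
  expect_error(parametric_decompose(mix_skew, Inf), "alpha is 0")
})

test_that("pooled-mixture volume is monotone in the mean-scale factor", {
  set.seed(57)
  cs <- c(1, 1.5, 2, 4, 8)
  for (rep in 1:10) {
    mix <- random_gaussian_mixture(n_dim = sample(1:3, 1),
                                   n_comp = sample(2:4, 1))
    for (q in c(0.5, 1, 2)) {
      g <- vapply(cs, function(cc) {
        gaussian_renyi(pool_parametric(scale_means(mix, cc)), q)
      }, numeric(1))
      expect_true(all(diff(g) >= -1e-9 * g[-length(g)]))
      expect_equal(g[1], gaussian_renyi(pool_parametric(mix), q))
    }
  }
  # all-zero means are fixed points of scaling
  mix0 <- gaussian_mixture_1d(c(0, 0), sds = c(1, 2))
  expect_equal(gaussian_renyi(pool_parametric(scale_means(mix0, 3)), 1),
               gaussian_renyi(pool_parametric(mix0), 1))
  expect_error(scale_means(mix0, 0.5), ">= 1")
})

test_that("the weighted log-determinant inequality holds on all valid inputs", {
  # equal matrices: equality
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_true(check_lemma2(list(S, S, S), c(0.2, 0.3, 0.5)))
  # scalar case: sqrt(2.5) >= 4^(1/4)
  expect_true(check_lemma2(list(matrix(1), matrix(4)), c(0.5, 0.5)))
  set.seed(58)
  for (rep in 1:500) {
    n_dim <- sample(1:4, 1)
    N <- sample(2:5, 1)
    expect_true(check_lemma2(random_psd_set(n_dim, N), random_prob_vector(N)))
  }
  expect_error(check_lemma2(list(diag(2), diag(3)), c(0.5, 0.5)),
               "common dimension")
})

test_that("parametric beta approaches a linear growth rate as components separate", {
  # unit variances, mean of component i at i * mu_o
  mu_grid <- seq(20, 60, by = 5)
  for (N in c(2, 4)) {
    beta <- vapply(mu_grid, function(mu_o) {
      parametric_decompose(gaussian_mixture_1d(seq_len(N) * mu_o, sds = 1),
                           1)$beta
    }, numeric(1))
    slopes <- diff(beta) / diff(mu_grid)
    rel_change <- abs(diff(slopes)) / slopes[-length(slopes)]
    expect_lt(max(tail(rel_change, 3)), 0.05)
  }
})
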
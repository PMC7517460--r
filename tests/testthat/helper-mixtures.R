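# Fixture generators shared across test files.

random_prob_vector <- function(n) {
  g <- rgamma(n, shape = 1)
  g / sum(g)
}

random_discrete_mixture <- function(N = NULL, n = NULL, equal_weights = FALSE) {
  if (is.null(N)) N <- sample(2:4, 1)
  if (is.null(n)) n <- sample(2:5, 1)
  w <- if (equal_weights) rep(1 / N, N) else random_prob_vector(N)
  P <- t(replicate(N, random_prob_vector(n)))
  discrete_mixture(w, P)
}

random_psd_set <- function(n_dim, N) {
  lapply(seq_len(N), function(i) {
    A <- matrix(rnorm(n_dim * n_dim), n_dim)
    tcrossprod(A)
  })
}

# Literal transcription of the discrete alpha formula, used as an
# independent oracle against the implementation.
alpha_oracle <- function(w, P, q) {
  if (abs(q - 1) < 1e-12) {
    ent <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      for (j in seq_len(ncol(P))) {
        if (P[i, j] > 0) ent[i] <- ent[i] - P[i, j] * log(P[i, j])
      }
    }
    return(exp(sum(w * ent)))
  }
  num <- 0
  den <- sum(w^q)
  for (i in seq_len(nrow(P))) {
    inner <- 0
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) inner <- inner + P[i, j]^q
    }
    num <- num + w[i]^q / den * inner
  }
  num^(1 / (1 - q))
}
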
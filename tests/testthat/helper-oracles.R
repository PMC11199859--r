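# Independent oracles and small fixtures shared across the test files.
# These deliberately re-derive quantities from first principles (double
# loops, eigendecompositions, closed forms) rather than calling the package
# code paths they are used to check.

# Brute-force NT-Xent: direct double-loop evaluation of the pair loss and
# the symmetrized batch mean over the pooled 2N projections.
ntxent_oracle_pair <- function(i, j, Z, tau) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  M <- nrow(Z)
  num <- exp(cosine(Z[i, ], Z[j, ]) / tau)
  den <- 0
  for (k in seq_len(M)) {
    if (k != i) den <- den + exp(cosine(Z[i, ], Z[k, ]) / tau)
  }
  -log(num / den)
}

ntxent_oracle_batch <- function(view_a, view_b, tau) {
  N <- nrow(view_a)
  Z <- rbind(view_a, view_b)
  total <- 0
  for (i in seq_len(N)) {
    total <- total + 0.5 * (ntxent_oracle_pair(i, N + i, Z, tau) +
                            ntxent_oracle_pair(N + i, i, Z, tau))
  }
  total / N
}

# Classical (kernel) PCA scores via eigendecomposition of the centered Gram
# matrix: score_j = sqrt(lambda_j) * v_j, sign fixed to match the package's
# largest-magnitude-loading convention applied to alpha = v / sqrt(lambda).
pca_scores_oracle <- function(X, n_comp) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  e <- eigen(Xc %*% t(Xc), symmetric = TRUE)
  v <- e$vectors[, seq_len(n_comp), drop = FALSE]
  lam <- e$values[seq_len(n_comp)]
  scores <- sweep(v, 2L, sqrt(pmax(lam, 0)), `*`)
  scores
}

# Tiny labeled batch used by many shape/identity tests.
tiny_batch <- function(n_per_class = 4L, n_classes = 2L, n_channels = 1L,
                       window = 32L, noise_sd = 0.3, seed = 7L) {
  generate_dataset(n_per_class, n_classes, n_channels, window, noise_sd,
                   seed = seed)
}

# Small encoder used throughout the tests (full-width defaults are not
# needed to exercise correctness).
tiny_encoder_config <- function() {
  encoder_config(channels = c(4L, 6L, 8L), kernel = 3L,
                 embed_dim = 8L, proj_dim = 4L)
}

# Benchmark-scale encoder for the end-to-end recovery study.
bench_encoder_config <- function() {
  encoder_config(channels = c(8L, 16L, 32L), embed_dim = 32L, proj_dim = 16L)
}

expect_batch_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a$X), dim(b$X))
  expect_lt(max(abs(a$X - b$X)), tol)
}
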
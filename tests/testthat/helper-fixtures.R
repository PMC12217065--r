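# Shared fixtures and independent oracles used across the suite.

# Independent 1-D analysis oracle: plain correlate-and-decimate with explicit
# modular indexing, written without reference to the package's internals.
oracle_dwt_step <- function(x, h, g) {
  N <- length(x)
  K <- N / 2
  a <- numeric(K)
  d <- numeric(K)
  for (k in 0:(K - 1)) {
    idx <- ((2 * k + seq_along(h) - 1) %% N) + 1
    a[k + 1] <- sum(h * x[idx])
    d[k + 1] <- sum(g * x[idx])
  }
  list(approx = a, detail = d)
}

# O(n^2) pairwise AUC oracle with half-credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A small standardized two-class image set for network tests.
make_tiny_set <- function(n_per_class = 10, side = 32, separability = 1,
                          seed = 7) {
  data <- generate_dataset(n_per_class, side, separability, seed = seed)
  standardize_images(data, ref = FALSE, side = side)
}

# Random probability vector on the m-simplex.
random_simplex <- function(m) {
  e <- rexp(m)
  e / sum(e)
}
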
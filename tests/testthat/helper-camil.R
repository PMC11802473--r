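# Shared helpers for the test suite.

# Relative error with an absolute floor: gradients that are analytically ~0
# drown in finite-difference round-off, so tiny absolute disagreements must
# not count as relative failures.
rel_err <- function(a, b, floor = 1e-4) {
  abs(a - b) / pmax(abs(a), abs(b), floor)
}

# A deliberately small model configuration for fast structural tests.
tiny_config <- function(...) {
  args <- list(d_model = 8L, n_layers = 1L, n_heads = 2L, input_dim = 4L,
               reduction_ratio = 2L, kernel_sizes = c(3L, 3L),
               n_landmarks = 8L, max_epochs = 2L, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(camil_config, args)
}

# A small, clearly separable synthetic dataset for training smoke tests.
tiny_dataset <- function(n_bags = 16L, seed = 3L, separation = 4,
                         feature_dim = 4L, bag_size_range = c(4L, 8L)) {
  generate_bags(synthetic_spec(
    n_bags = n_bags, bag_size_range = bag_size_range, witness_rate = 0.4,
    feature_dim = feature_dim, separation = separation, noise_sd = 1,
    seed = seed))
}

# Brute-force single-head softmax attention, written independently of the
# package internals (double loops, no shared code).
brute_attention <- function(H, Wq, bq, Wk, bk, Wv, bv, Wo, bo) {
  N <- nrow(H); d <- ncol(Wq)
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  for (i in seq_len(N)) {
    Q[i, ] <- Q[i, ] + bq
    K[i, ] <- K[i, ] + bk
    V[i, ] <- V[i, ] + bv
  }
  out <- matrix(0, N, d)
  for (i in seq_len(N)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(N)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  res <- out %*% Wo
  for (i in seq_len(N)) res[i, ] <- res[i, ] + bo
  res
}

# Pairwise Mann-Whitney AUC enumeration, independent of compute_auc.
brute_auc <- function(y, p, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  pos <- p[y == 1L]; neg <- p[y == 0L]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b && ties == "half") 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
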
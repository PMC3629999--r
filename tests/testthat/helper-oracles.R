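# Independent oracles and tiny fixtures shared across the suite.

# Truncated Neumann series for the relevance propagation:
# (1 - alpha) * sum_k alpha^k S^k q
neumann_oracle <- function(s_values, q, alpha, k_max = 400) {
  acc <- q
  term <- q
  for (k in seq_len(k_max)) {
    term <- alpha * (s_values %*% term)
    acc <- acc + term
  }
  as.numeric((1 - alpha) * acc)
}

# Pairwise-concordance AUC with half credit for ties, by exhaustive
# enumeration of (positive, negative) pairs.
concordance_auc <- function(scores, positives) {
  pos <- scores[positives]
  neg <- scores[-positives]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Textbook Pearson correlation (explicit moments, no stats::cor).
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# Random column-stochastic matrix (no zero columns).
random_column_stochastic <- function(n) {
  m <- matrix(stats::runif(n * n, min = 0.01), n, n)
  sweep(m, 2, colSums(m), `/`)
}

make_sim <- function(values, ids = NULL, normalized = FALSE) {
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(values)))
  similarity_matrix(values, ids = ids, normalized = normalized)
}

# Similarity matrices whose IDs line up with make_net()'s two axes.
make_msim <- function(values, normalized = FALSE) {
  make_sim(values, ids = paste0("miR-", seq_len(nrow(values))),
           normalized = normalized)
}
make_psim <- function(values, normalized = FALSE) {
  make_sim(values, ids = paste0("OMIM-", seq_len(nrow(values))),
           normalized = normalized)
}

make_net <- function(adj) {
  assoc_network(adj,
                paste0("miR-", seq_len(nrow(adj))),
                paste0("OMIM-", seq_len(ncol(adj))))
}

# A small but non-trivial fixture with planted signal.
small_signal_data <- function(seed = 11) {
  generate_synthetic(synthetic_spec(n_mirnas = 20, n_phenotypes = 10,
                                    n_blocks = 2, seed = seed))
}
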
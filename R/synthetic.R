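# Block-structured synthetic data emulating the statistical assumption the
# inference methods rest on: functionally related miRNAs (high mutual
# similarity) tend to associate with phenotypically similar diseases.

#' Specification for a synthetic benchmark
#'
#' miRNAs and phenotypes are partitioned into `n_blocks` paired
#' communities. Pairwise similarities are drawn around `within_sim` inside
#' a block and `between_sim` across blocks (normal jitter of sd
#' `sim_noise`, truncated to \[0, 1\], symmetrized, diagonal fixed at 1).
#' Associations are Bernoulli edges with probability `edge_prob_matched`
#' between paired blocks and `edge_prob_unmatched` otherwise. The defaults
#' are the study conditions used throughout the package's evaluation:
#' 60 miRNAs x 30 phenotypes in 3 blocks with a strong similarity contrast
#' (0.7 vs 0.1) and a 15-fold edge-probability contrast (0.3 vs 0.02).
#'
#' @param n_mirnas,n_phenotypes Entity counts (>= 1).
#' @param n_blocks Number of paired communities.
#' @param within_sim,between_sim Mean similarity inside / across blocks.
#' @param sim_noise SD of the similarity jitter.
#' @param edge_prob_matched,edge_prob_unmatched Association probabilities
#'   within paired blocks and elsewhere.
#' @param seed Integer RNG seed; same seed, same dataset, byte for byte.
#' @return A `synthetic_spec` list, validated.
#' @export
synthetic_spec <- function(n_mirnas = 60L, n_phenotypes = 30L, n_blocks = 3L,
                           within_sim = 0.7, between_sim = 0.1,
                           sim_noise = 0.05, edge_prob_matched = 0.3,
                           edge_prob_unmatched = 0.02, seed = 1L) {
  spec <- list(n_mirnas = as.integer(n_mirnas),
               n_phenotypes = as.integer(n_phenotypes),
               n_blocks = as.integer(n_blocks),
               within_sim = within_sim, between_sim = between_sim,
               sim_noise = sim_noise,
               edge_prob_matched = edge_prob_matched,
               edge_prob_unmatched = edge_prob_unmatched,
               seed = as.integer(seed))
  with(spec, {
    if (n_mirnas < 1 || n_phenotypes < 1 || n_blocks < 1)
      stop_parameter("counts must all be >= 1")
    if (n_blocks > min(n_mirnas, n_phenotypes))
      stop_parameter("n_blocks exceeds an entity count")
    probs <- c(within_sim, between_sim, edge_prob_matched, edge_prob_unmatched)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
      stop_parameter("similarity means and edge probabilities must lie in [0, 1]")
    if (within_sim < between_sim)
      stop_parameter("within_sim must be >= between_sim (use equality for a null spec)")
    if (sim_noise < 0) stop_parameter("sim_noise must be >= 0")
  })
  structure(spec, class = "synthetic_spec")
}

block_labels <- function(n, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n))
}

sim_from_blocks <- function(labels, within, between, noise, ids) {
  n <- length(labels)
  mu <- ifelse(outer(labels, labels, `==`), within, between)
  s <- mu + matrix(stats::rnorm(n * n, 0, noise), n, n)
  s <- (s + t(s)) / 2
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  similarity_matrix(s, ids = ids)
}

#' Generate a synthetic similarity/association benchmark
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `sm` and `sp` (miRNA / phenotype
#'   [similarity_matrix()] objects), `net` (an [assoc_network()]),
#'   and the ground-truth block labels `mirna_blocks`, `phenotype_blocks`.
#' @examples
#' d <- generate_synthetic(synthetic_spec(n_mirnas = 12, n_phenotypes = 6,
#'                                        n_blocks = 2, seed = 42))
#' degree_stats(d$net)$n_edges
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    mb <- block_labels(spec$n_mirnas, spec$n_blocks)
    pb <- block_labels(spec$n_phenotypes, spec$n_blocks)
    mids <- sprintf("miR-%03d", seq_len(spec$n_mirnas))
    pids <- sprintf("OMIM-%06d", 100000L + seq_len(spec$n_phenotypes))
    sm <- sim_from_blocks(mb, spec$within_sim, spec$between_sim,
                          spec$sim_noise, mids)
    sp <- sim_from_blocks(pb, spec$within_sim, spec$between_sim,
                          spec$sim_noise, pids)
    p_edge <- ifelse(outer(mb, pb, `==`), spec$edge_prob_matched,
                     spec$edge_prob_unmatched)
    adj <- matrix(stats::rbinom(length(p_edge), 1, p_edge),
                  spec$n_mirnas, spec$n_phenotypes)
    list(sm = sm, sp = sp,
         net = assoc_network(adj, mids, pids),
         mirna_blocks = stats::setNames(mb, mids),
         phenotype_blocks = stats::setNames(pb, pids))
  })
}

#' Replace a similarity matrix by structureless noise
#'
#' Symmetric uniform noise on \[0, 1\] with unit diagonal and the same IDs:
#' the "channel knocked out" control used to show that each inference
#' method responds to its own similarity channel.
#'
#' @param s A [similarity_matrix()] supplying size and IDs.
#' @param seed Integer RNG seed.
#' @return A [similarity_matrix()] with no community structure.
#' @export
noise_similarity <- function(s, seed = 1L) {
  stopifnot(inherits(s, "similarity_matrix"))
  n <- length(s$ids)
  with_seed(seed, {
    x <- matrix(stats::runif(n * n), n, n)
    x <- (x + t(x)) / 2
    diag(x) <- 1
    similarity_matrix(x, ids = s$ids)
  })
}

#' Degree-preserving null model by checkerboard edge swaps
#'
#' Repeatedly picks two edges (i1, j1), (i2, j2) and, when the crossed
#' pairs are absent, rewires them to (i1, j2), (i2, j1). Both degree
#' sequences are exactly preserved while the coupling between similarity
#' structure and associations is destroyed. The default number of
#' attempted swaps is ten times the edge count, a standard mixing
#' heuristic for bipartite null models.
#'
#' @param net An [assoc_network()].
#' @param seed Integer RNG seed.
#' @param n_swaps Number of attempted swaps (valid ones are applied).
#' @return A shuffled [assoc_network()] with identical degree sequences.
#' @export
generate_null_by_shuffle <- function(net, seed = 1L,
                                     n_swaps = 10L * sum(net$adjacency)) {
  stopifnot(inherits(net, "assoc_network"))
  adj <- net$adjacency
  edges <- which(adj == 1, arr.ind = TRUE)
  if (nrow(edges) < 2) {
    warning("fewer than two edges; returning the network unchanged")
    return(net)
  }
  with_seed(seed, {
    for (k in seq_len(n_swaps)) {
      pick <- sample.int(nrow(edges), 2L)
      e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
      if (e1[1] == e2[1] || e1[2] == e2[2]) next
      if (adj[e1[1], e2[2]] == 1 || adj[e2[1], e1[2]] == 1) next
      adj[e1[1], e1[2]] <- 0; adj[e2[1], e2[2]] <- 0
      adj[e1[1], e2[2]] <- 1; adj[e2[1], e1[2]] <- 1
      edges[pick[1], 2] <- e2[2]
      edges[pick[2], 2] <- e1[2]
    }
  })
  assoc_network(adj, net$mirna_ids, net$phenotype_ids,
                dropped_edges = net$dropped_edges)
}

#' Random bipartite network with fixed size and edge count
#'
#' Draws a network with exactly `n_edges` associations over `n_mirnas` x
#' `n_phenotypes`, every entity receiving at least one edge (requires
#' `n_edges >= max(n_mirnas, n_phenotypes)`). Useful for shape-matched
#' fixtures whose count-derived statistics (average degrees) are fixed by
#' construction.
#'
#' @param n_mirnas,n_phenotypes,n_edges Network dimensions.
#' @param seed Integer RNG seed.
#' @return An [assoc_network()].
#' @export
generate_fixed_size_network <- function(n_mirnas, n_phenotypes, n_edges,
                                        seed = 1L) {
  if (n_edges < max(n_mirnas, n_phenotypes)) {
    stop_parameter("need at least max(n_mirnas, n_phenotypes) edges to cover every entity")
  }
  if (n_edges > n_mirnas * n_phenotypes) {
    stop_parameter("n_edges exceeds the number of available pairs")
  }
  mids <- sprintf("miR-%03d", seq_len(n_mirnas))
  pids <- sprintf("OMIM-%06d", 100000L + seq_len(n_phenotypes))
  with_seed(seed, {
    adj <- matrix(0, n_mirnas, n_phenotypes)
    # cover both axes with max(n, m) edges: randomly permuted cyclic matching
    k <- max(n_mirnas, n_phenotypes)
    rows <- sample.int(n_mirnas)[((seq_len(k) - 1) %% n_mirnas) + 1]
    cols <- sample.int(n_phenotypes)[((seq_len(k) - 1) %% n_phenotypes) + 1]
    adj[cbind(rows, cols)] <- 1
    free <- which(adj == 0)
    need <- n_edges - sum(adj)
    if (need > 0) adj[sample(free, need)] <- 1
    assoc_network(adj, mids, pids)
  })
}
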
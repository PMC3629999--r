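# The three scoring schemes. MBSI and PBSI are neighbourhood-weighted
# recommendations on one similarity channel; NetCBI couples both channels
# through graph-Laplacian relevance propagation and a network-consistency
# correlation.

score_table <- function(scores, mirna_ids, phenotype_ids, method,
                        alpha = NA_real_, beta = NA_real_) {
  dimnames(scores) <- list(mirna_ids, phenotype_ids)
  structure(list(mirna_ids = mirna_ids, phenotype_ids = phenotype_ids,
                 scores = scores, method = method,
                 alpha = alpha, beta = beta),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table [%s]: %d miRNAs x %d phenotypes\n", x$method,
              length(x$mirna_ids), length(x$phenotype_ids)))
  if (!is.na(x$alpha)) cat(sprintf("alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

check_alignment <- function(ids, net_ids, what) {
  if (!identical(as.character(ids), as.character(net_ids))) {
    stop_validation("%s IDs of the similarity matrix do not match the network axis", what)
  }
}

#' miRNA-based similarity inference (MBSI)
#'
#' Scores each miRNA-phenotype pair (i, j) as the similarity-weighted
#' average of the other miRNAs' associations with phenotype j:
#' \deqn{v_{ij} = \frac{\sum_{l \ne i} S(m_i, m_l)\, a_{lj}}
#'                     {\sum_{l \ne i} S(m_i, m_l)}}
#' A miRNA whose similarity to every other miRNA is zero has no
#' recommendation support; its scores are defined as 0. All scores lie in
#' \[0, 1\] and are invariant to positive rescaling of the similarities.
#'
#' @param sm Un-normalized miRNA [similarity_matrix()], aligned with the
#'   network's miRNA axis.
#' @param net An [assoc_network()].
#' @return A `score_table` with `method = "MBSI"`.
#' @export
mbsi_scores <- function(sm, net) {
  stopifnot(inherits(sm, "similarity_matrix"), inherits(net, "assoc_network"))
  check_alignment(sm$ids, net$mirna_ids, "miRNA")
  w <- sm$values
  diag(w) <- 0
  denom <- rowSums(w)
  num <- w %*% net$adjacency
  scores <- num / ifelse(denom > 0, denom, 1)
  scores[denom == 0, ] <- 0
  score_table(scores, net$mirna_ids, net$phenotype_ids, "MBSI")
}

#' Phenotype-based similarity inference (PBSI)
#'
#' Scores each miRNA-phenotype pair (i, j) as the similarity-weighted
#' average of miRNA i's associations with the other phenotypes:
#' \deqn{v_{ij} = \frac{\sum_{l \ne j} S(p_j, p_l)\, a_{il}}
#'                     {\sum_{l \ne j} S(p_j, p_l)}}
#' Zero-support phenotypes score 0, as in [mbsi_scores()].
#'
#' @param sp Un-normalized phenotype [similarity_matrix()], aligned with
#'   the network's phenotype axis.
#' @param net An [assoc_network()].
#' @return A `score_table` with `method = "PBSI"`.
#' @export
pbsi_scores <- function(sp, net) {
  stopifnot(inherits(sp, "similarity_matrix"), inherits(net, "assoc_network"))
  check_alignment(sp$ids, net$phenotype_ids, "phenotype")
  w <- sp$values
  diag(w) <- 0
  denom <- rowSums(w)            # support for target phenotype j: sum_l S(p_j, p_l)
  num <- net$adjacency %*% t(w)  # [i, j] = sum_l a_il S(p_j, p_l)
  scores <- sweep(num, 2, ifelse(denom > 0, denom, 1), `/`)
  scores[, denom == 0] <- 0
  score_table(scores, net$mirna_ids, net$phenotype_ids, "PBSI")
}

#' Graph-Laplacian relevance propagation
#'
#' Solves the smoothness-vs-fidelity trade-off on a similarity graph: the
#' relevance vector x minimizes a graph-smoothness penalty (connected
#' entities get similar scores) plus a fidelity term tying x to the binary
#' query indicator q, with mixing weight `alpha`. The closed form is
#' \eqn{x = (1-\alpha)(I - \alpha \bar{S})^{-1} q}, computed here by a
#' linear solve (never an explicit inverse); the residual is checked
#' against `1e-8 * ||q||`.
#'
#' For a column-stochastic \eqn{\bar{S}} the propagation conserves mass
#' (`sum(x) == sum(q)`), and as `alpha` approaches 0 the solution tends to
#' the query itself.
#'
#' @param s_norm Column-normalized [similarity_matrix()] (see
#'   [normalize_columns()]).
#' @param q A [query_indicator()] on the matching axis, or a bare numeric
#'   vector of matching length.
#' @param alpha Smoothing parameter in (0, 1).
#' @return Named numeric vector of relevance scores, aligned to the axis IDs.
#' @export
laplacian_relevance <- function(s_norm, q, alpha) {
  stopifnot(inherits(s_norm, "similarity_matrix"))
  check_in_unit_interval(alpha, "alpha")
  if (!s_norm$normalized) {
    stop_validation("similarity matrix must be column-normalized before propagation")
  }
  qv <- if (inherits(q, "query_indicator")) q$vector else as.numeric(q)
  n <- length(s_norm$ids)
  if (length(qv) != n) stop_validation("query vector length %d != axis size %d",
                                       length(qv), n)
  a_mat <- diag(n) - alpha * s_norm$values
  x <- tryCatch(solve(a_mat, (1 - alpha) * qv),
                error = function(e) stop_numerical(
                  "linear solve failed (alpha = %g, n = %d): %s",
                  alpha, n, conditionMessage(e)))
  resid <- sqrt(sum((a_mat %*% x - (1 - alpha) * qv)^2))
  if (resid > 1e-8 * max(sqrt(sum(qv^2)), 1)) {
    stop_numerical("relevance solve residual %.3g exceeds tolerance", resid)
  }
  names(x) <- s_norm$ids
  x
}

# Relevance profiles for every single-entity query at once: column i of the
# result is the relevance vector for query indicator e_i, i.e.
# (1 - alpha) * (I - alpha * S)^{-1}.
relevance_basis <- function(s_norm, alpha) {
  stopifnot(inherits(s_norm, "similarity_matrix"), s_norm$normalized)
  check_in_unit_interval(alpha, "alpha")
  n <- length(s_norm$ids)
  out <- (1 - alpha) * solve(diag(n) - alpha * s_norm$values)
  dimnames(out) <- list(s_norm$ids, s_norm$ids)
  out
}

# Pearson correlation of each column of X against v; columns (or v) with
# zero variance score 0 rather than NA.
cor_columns_vs <- function(x_mat, v, eps = 1e-300) {
  n <- length(v)
  sv <- sum(v); svv <- sum(v * v)
  den_v <- n * svv - sv * sv
  su <- colSums(x_mat); suu <- colSums(x_mat * x_mat)
  suv <- as.numeric(crossprod(x_mat, v))
  num <- n * suv - su * sv
  den_u <- n * suu - su * su
  den <- sqrt(pmax(den_u, 0) * max(den_v, 0))
  out <- ifelse(den > eps & den_v > eps & den_u > eps, num / den, 0)
  pmin(1, pmax(-1, out))
}

#' Network-consistency scores for one query miRNA (NetCBI)
#'
#' For a query miRNA, relevance to all miRNAs is propagated over the
#' miRNA similarity network (weight `alpha`); for each candidate phenotype
#' j, relevance of all phenotypes to j is propagated over the phenotype
#' similarity network (weight `beta`). The NetCBI score of phenotype j is
#' the Pearson correlation between the n-vectors \eqn{a \tilde{p}_j} (known
#' associations projected through the phenotype relevance profile) and
#' \eqn{\tilde{m}} (the miRNA relevance profile): high when known edges
#' connect miRNAs relevant to the query with phenotypes relevant to the
#' candidate. Degenerate correlations (either vector of zero variance,
#' e.g. an empty network) are defined as 0.
#'
#' @param sm_norm,sp_norm Column-normalized similarity matrices for the
#'   miRNA and phenotype axes.
#' @param net An [assoc_network()] aligned with both.
#' @param query A single-miRNA [query_indicator()] (or one miRNA ID).
#' @param alpha,beta Smoothing parameters in (0, 1).
#' @return Named numeric vector of scores in \[-1, 1\], one per phenotype.
#' @export
netcbi_scores <- function(sm_norm, sp_norm, net, query, alpha, beta) {
  stopifnot(inherits(net, "assoc_network"))
  check_alignment(sm_norm$ids, net$mirna_ids, "miRNA")
  check_alignment(sp_norm$ids, net$phenotype_ids, "phenotype")
  if (!inherits(query, "query_indicator")) {
    query <- query_indicator("mirna", net$mirna_ids, query)
  }
  if (query$axis != "mirna" || length(query$index) != 1L) {
    stop_validation("NetCBI scoring is defined for a single query miRNA")
  }
  mtil <- laplacian_relevance(sm_norm, query, alpha)
  ptil <- relevance_basis(sp_norm, beta)   # column j = relevance profile of phenotype j
  if (sum(net$adjacency) == 0) {
    warning("association network has no edges; all NetCBI scores are 0")
  }
  u <- net$adjacency %*% ptil              # column j = a %*% p~_j
  out <- cor_columns_vs(u, mtil)
  names(out) <- net$phenotype_ids
  out
}

#' Full NetCBI score table over all miRNA-phenotype pairs
#'
#' Runs [netcbi_scores()] for every miRNA as query, sharing the two
#' relevance-profile factorizations across queries.
#'
#' @inheritParams netcbi_scores
#' @return A `score_table` with `method = "NetCBI"`.
#' @export
netcbi_score_table <- function(sm_norm, sp_norm, net, alpha, beta) {
  check_alignment(sm_norm$ids, net$mirna_ids, "miRNA")
  check_alignment(sp_norm$ids, net$phenotype_ids, "phenotype")
  mtil_all <- relevance_basis(sm_norm, alpha)
  ptil <- relevance_basis(sp_norm, beta)
  u <- net$adjacency %*% ptil
  n <- length(net$mirna_ids); m <- length(net$phenotype_ids)
  scores <- matrix(0, n, m)
  for (i in seq_len(n)) scores[i, ] <- cor_columns_vs(u, mtil_all[, i])
  score_table(scores, net$mirna_ids, net$phenotype_ids, "NetCBI",
              alpha = alpha, beta = beta)
}

# LOOCV score matrix for NetCBI: row i holds the scores for query miRNA i
# computed with miRNA i's association row zeroed out. Zeroing one row of
# `a` is a rank-one change to a %*% ptil, so all cross-products are
# corrected in closed form instead of redoing a matmul per query.
netcbi_loocv_matrix <- function(mtil_all, ptil, adjacency, eps = 1e-300) {
  u <- adjacency %*% ptil                 # n x m
  n <- nrow(u); m <- ncol(u)
  cu <- crossprod(u, mtil_all)            # m x n: sum_k u[k,j] mtil[k,i]
  su <- colSums(u); suu <- colSums(u * u)
  sv <- colSums(mtil_all); svv <- colSums(mtil_all * mtil_all)
  d <- diag(mtil_all)                     # mtil[i, i], the entry dropped with row i
  suv1 <- t(cu) - u * d                   # n x m: corrected sum(u' * v)
  su1 <- matrix(su, n, m, byrow = TRUE) - u
  suu1 <- matrix(suu, n, m, byrow = TRUE) - u * u
  num <- n * suv1 - su1 * sv              # sv recycles down rows
  den_u <- pmax(n * suu1 - su1 * su1, 0)
  den_v <- pmax(n * svv - sv * sv, 0)     # length n, recycles down rows
  den <- sqrt(den_u * den_v)
  scores <- ifelse(den > eps, num / den, 0)
  pmin(pmax(scores, -1), 1)
}

#' Rank unknown pairs by prediction score
#'
#' Excludes known associations, sorts the remaining pairs by score
#' (descending), breaks ties lexicographically on (miRNA ID, phenotype ID)
#' for reproducibility, and returns the head of the ranking.
#'
#' @param table A `score_table`.
#' @param net The [assoc_network()] whose known edges are excluded.
#' @param top_k Number of predictions to return; if it exceeds the number
#'   of unknown pairs, all are returned with a message.
#' @return A `data.frame` with columns `rank`, `mirna_id`, `phenotype_id`,
#'   `score`.
#' @export
rank_predictions <- function(table, net, top_k = 100L) {
  stopifnot(inherits(table, "score_table"), inherits(net, "assoc_network"))
  if (!identical(table$mirna_ids, net$mirna_ids) ||
      !identical(table$phenotype_ids, net$phenotype_ids)) {
    stop_validation("score table and network axes are not aligned")
  }
  if (top_k < 0) stop_parameter("top_k must be non-negative")
  unknown <- which(net$adjacency == 0, arr.ind = TRUE)
  df <- data.frame(mirna_id = table$mirna_ids[unknown[, 1]],
                   phenotype_id = table$phenotype_ids[unknown[, 2]],
                   score = table$scores[unknown],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$mirna_id, df$phenotype_id), , drop = FALSE]
  if (top_k > nrow(df)) {
    message(sprintf("top_k = %d exceeds the %d unknown pairs; returning all",
                    top_k, nrow(df)))
    top_k <- nrow(df)
  }
  df <- utils::head(df, top_k)
  rownames(df) <- NULL
  if (nrow(df) > 0) df <- cbind(rank = seq_len(nrow(df)), df)
  else df <- cbind(data.frame(rank = integer(0)), df)
  df
}
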
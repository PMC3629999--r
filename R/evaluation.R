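# Leave-one-out cross-validation with the method-specific removal rules,
# ROC construction by threshold sweep, and trapezoidal AUC.

#' ROC curve and AUC from scores and a positive set
#'
#' Sweeps the distinct score values in descending order as thresholds; at
#' each threshold the true-positive fraction (TPF, sensitivity) is the
#' share of positives scoring at or above it and the false-positive
#' fraction (FPF) the share of negatives doing so. The curve is anchored
#' at (0, 0) and (1, 1) and integrated by the trapezoidal rule, which
#' equals the rank statistic P(score_pos > score_neg) + 1/2 P(tie).
#'
#' @param scores Numeric vector of candidate scores.
#' @param positives Indices (or logical mask) of the true positives.
#' @return A list with `auc` and `curve`, a `data.frame` of
#'   `(threshold, FPF, TPF)` rows including the anchor points
#'   (anchors carry `NA` thresholds).
#' @export
roc_auc <- function(scores, positives) {
  scores <- as.numeric(scores)
  if (is.logical(positives)) positives <- which(positives)
  pos <- logical(length(scores))
  pos[positives] <- TRUE
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_validation("AUC undefined: need at least one positive and one negative")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpf <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpf <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- data.frame(threshold = c(NA, thr, NA),
                      FPF = c(0, fpf, 1), TPF = c(0, tpf, 1))
  # drop a duplicated terminal point when the lowest threshold already hits (1,1)
  k <- nrow(curve)
  if (curve$FPF[k - 1] == 1 && curve$TPF[k - 1] == 1) curve <- curve[-k, ]
  auc <- sum(diff(curve$FPF) * (utils::head(curve$TPF, -1) + utils::tail(curve$TPF, -1)) / 2)
  list(auc = auc, curve = curve)
}

# Rank-based AUC (identical to the trapezoid over the distinct-threshold
# sweep; ties get half credit). Used in the inner CV loops where the ROC
# points themselves are not needed.
auc_rank <- function(scores, pos_mask) {
  n_pos <- sum(pos_mask); n_neg <- sum(!pos_mask)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos_mask]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

cv_report <- function(method, per_query, params = NULL, skipped = character(0),
                      excluded = character(0)) {
  aucs <- vapply(per_query, `[[`, numeric(1), "auc")
  structure(list(method = method,
                 per_query = per_query,
                 average_auc = if (length(aucs)) mean(aucs) else NA_real_,
                 params = params,
                 skipped_queries = skipped,
                 excluded_queries = excluded),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s]: %d queries, average AUC = %.4f\n",
              x$method, length(x$per_query), x$average_auc))
  if (!is.null(x$params)) {
    cat(sprintf("params: alpha = %g, beta = %g\n", x$params$alpha, x$params$beta))
  }
  invisible(x)
}

query_roc_entry <- function(id, scores, pos_mask) {
  r <- roc_auc(scores, which(pos_mask))
  list(id = id, auc = r$auc, roc = r$curve)
}

#' Leave-one-out cross-validation over miRNA queries
#'
#' One iteration per miRNA with at least one known association: that
#' miRNA's entire adjacency row is removed (all its disease associations,
#' including the targets being recovered), all phenotypes are scored for
#' it on the reduced network, and an ROC/AUC is computed with the removed
#' phenotypes as positives and all others as negatives. Queries with no
#' associations are skipped; queries with no negatives (associated with
#' every phenotype) have an undefined ROC and are excluded from the
#' average with a warning.
#'
#' @param method `"MBSI"` or `"NetCBI"` (the two miRNA-query methods).
#' @param sm Un-normalized miRNA [similarity_matrix()].
#' @param sp Un-normalized phenotype [similarity_matrix()] (required for
#'   NetCBI; ignored by MBSI).
#' @param net An [assoc_network()].
#' @param alpha,beta Smoothing parameters (NetCBI only).
#' @return A `cv_report`: per-query ROC curves and AUCs plus their
#'   unweighted mean in `average_auc`.
#' @export
loocv_mirna_query <- function(method = c("MBSI", "NetCBI"), sm, sp = NULL, net,
                              alpha = 0.1, beta = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(net, "assoc_network"))
  deg <- rowSums(net$adjacency)
  queries <- which(deg >= 1)
  if (length(queries) == 0) stop_validation("no miRNA has any association to hold out")
  skipped <- net$mirna_ids[deg == 0]
  excluded <- character(0)
  m <- length(net$phenotype_ids)

  if (method == "NetCBI") {
    sm_norm <- normalize_columns(sm)
    sp_norm <- normalize_columns(sp)
    mtil_all <- relevance_basis(sm_norm, alpha)
    ptil <- relevance_basis(sp_norm, beta)
    loocv_scores <- netcbi_loocv_matrix(mtil_all, ptil, net$adjacency)
  }

  per_query <- list()
  for (i in queries) {
    pos <- net$adjacency[i, ] == 1
    if (all(pos)) {
      excluded <- c(excluded, net$mirna_ids[i])
      next
    }
    if (method == "MBSI") {
      reduced <- net
      reduced$adjacency[i, ] <- 0
      sc <- mbsi_scores(sm, reduced)$scores[i, ]
    } else {
      sc <- loocv_scores[i, ]
    }
    per_query[[length(per_query) + 1L]] <-
      query_roc_entry(net$mirna_ids[i], sc, pos)
  }
  if (length(excluded)) {
    warning(sprintf("%d quer%s with no negative phenotypes excluded from the average: %s",
                    length(excluded), if (length(excluded) == 1) "y" else "ies",
                    paste(excluded, collapse = ", ")))
  }
  params <- if (method == "NetCBI") list(alpha = alpha, beta = beta) else NULL
  cv_report(method, per_query, params, skipped, excluded)
}

#' Leave-one-out cross-validation over phenotype queries (PBSI)
#'
#' One iteration per phenotype with at least one association: its
#' adjacency column is removed, all miRNAs are scored for it with PBSI on
#' the reduced network, and the removed miRNAs are the positives. (The
#' PBSI sum over phenotypes `l != j` never reads column j, so the reduced
#' scores coincide with full-data scores; the removal is performed anyway
#' for protocol uniformity.)
#'
#' @param sp Un-normalized phenotype [similarity_matrix()].
#' @param net An [assoc_network()].
#' @return A `cv_report` for method `"PBSI"`.
#' @export
loocv_phenotype_query <- function(sp, net) {
  stopifnot(inherits(net, "assoc_network"))
  deg <- colSums(net$adjacency)
  queries <- which(deg >= 1)
  if (length(queries) == 0) stop_validation("no phenotype has any association to hold out")
  skipped <- net$phenotype_ids[deg == 0]
  excluded <- character(0)
  per_query <- list()
  for (j in queries) {
    pos <- net$adjacency[, j] == 1
    if (all(pos)) {
      excluded <- c(excluded, net$phenotype_ids[j])
      next
    }
    reduced <- net
    reduced$adjacency[, j] <- 0
    sc <- pbsi_scores(sp, reduced)$scores[, j]
    per_query[[length(per_query) + 1L]] <-
      query_roc_entry(net$phenotype_ids[j], sc, pos)
  }
  if (length(excluded)) {
    warning(sprintf("%d quer%s with no negative miRNAs excluded from the average: %s",
                    length(excluded), if (length(excluded) == 1) "y" else "ies",
                    paste(excluded, collapse = ", ")))
  }
  cv_report("PBSI", per_query, NULL, skipped, excluded)
}

# Lean NetCBI LOOCV: average AUC only, reusing precomputed relevance bases.
# `queries` restricts which miRNA rows are evaluated (default: all with
# at least one association and at least one negative).
netcbi_loocv_auc <- function(mtil_all, ptil, adjacency, queries = NULL) {
  scores <- netcbi_loocv_matrix(mtil_all, ptil, adjacency)
  m <- ncol(adjacency)
  deg <- rowSums(adjacency)
  if (is.null(queries)) queries <- seq_len(nrow(adjacency))
  queries <- queries[deg[queries] >= 1 & deg[queries] < m]
  if (length(queries) == 0) return(NA_real_)
  aucs <- vapply(queries, function(i) {
    auc_rank(scores[i, ], adjacency[i, ] == 1)
  }, numeric(1))
  mean(aucs)
}
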
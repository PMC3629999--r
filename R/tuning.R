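# Smoothing-parameter selection for NetCBI: exhaustive grid search under
# LOOCV, and a nested LOOCV giving an unbiased outer AUC estimate.

default_grid <- function() seq(0.1, 0.9, by = 0.1)

check_grid <- function(g, name) {
  if (length(g) == 0) stop_parameter("%s grid is empty", name)
  if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1)) {
    stop_parameter("%s grid values must lie in the open interval (0, 1)", name)
  }
  sort(unique(as.numeric(g)))
}

# Maximal-AUC grid point; ties resolved to the smallest (alpha, beta)
# lexicographically so runs are reproducible.
select_best <- function(grid_df) {
  best <- grid_df[grid_df$auc >= max(grid_df$auc) - 1e-12, , drop = FALSE]
  best <- best[order(best$alpha, best$beta), , drop = FALSE]
  list(alpha = best$alpha[1], beta = best$beta[1], auc = best$auc[1])
}

#' Grid search over NetCBI smoothing parameters
#'
#' Runs miRNA-query LOOCV with NetCBI at every (alpha, beta) combination
#' and records the average AUC; the maximizer is selected (ties broken to
#' the smallest pair).
#'
#' @param sm,sp Un-normalized similarity matrices (miRNA, phenotype axes).
#' @param net An [assoc_network()].
#' @param alpha_grid,beta_grid Candidate values in (0, 1); default
#'   0.1 to 0.9 in steps of 0.1.
#' @return A `tuning_result`: `grid` (a `data.frame` with columns `alpha`,
#'   `beta`, `auc`) and `selected` (list with `alpha`, `beta`, `auc`).
#' @export
grid_search <- function(sm, sp, net, alpha_grid = default_grid(),
                        beta_grid = default_grid()) {
  alpha_grid <- check_grid(alpha_grid, "alpha")
  beta_grid <- check_grid(beta_grid, "beta")
  sm_norm <- normalize_columns(sm)
  sp_norm <- normalize_columns(sp)
  mtil <- lapply(alpha_grid, function(a) relevance_basis(sm_norm, a))
  ptil <- lapply(beta_grid, function(b) relevance_basis(sp_norm, b))
  grid_df <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                         KEEP.OUT.ATTRS = FALSE)
  grid_df$auc <- mapply(function(ai, bi) {
    netcbi_loocv_auc(mtil[[ai]], ptil[[bi]], net$adjacency)
  }, match(grid_df$alpha, alpha_grid), match(grid_df$beta, beta_grid))
  structure(list(grid = grid_df, selected = select_best(grid_df)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result: %d grid points, selected alpha = %g, beta = %g (AUC = %.4f)\n",
              nrow(x$grid), x$selected$alpha, x$selected$beta, x$selected$auc))
  if (!is.null(x$outer_auc)) {
    cat(sprintf("nested outer AUC = %.4f; per-fold alpha = %.4f +/- %.4f, beta = %.4f +/- %.4f\n",
                x$outer_auc, mean(x$selected_per_fold$alpha),
                stats::sd(x$selected_per_fold$alpha),
                mean(x$selected_per_fold$beta), stats::sd(x$selected_per_fold$beta)))
  }
  invisible(x)
}

#' Nested leave-one-out cross-validation for NetCBI
#'
#' Each miRNA in turn is set aside as the validation case (its association
#' row removed); an inner LOOCV over the remaining miRNAs selects
#' (alpha, beta) by grid search, and the validation miRNA is then scored
#' with the selected parameters. The outer AUC is the mean of the
#' validation AUCs and is an unbiased estimate of generalization
#' performance; the per-fold parameter selections are reported with their
#' mean and standard deviation. The similarity matrices (side information,
#' not association labels) stay full-size throughout.
#'
#' @inheritParams grid_search
#' @return A `tuning_result` with additional fields `outer_auc`,
#'   `selected_per_fold` (a `data.frame` with `fold_id`, `alpha`, `beta`,
#'   `inner_auc`, `validation_auc`) and `selected` (the grid choice over
#'   the full data, for downstream prediction).
#' @export
nested_loocv <- function(sm, sp, net, alpha_grid = default_grid(),
                         beta_grid = default_grid()) {
  alpha_grid <- check_grid(alpha_grid, "alpha")
  beta_grid <- check_grid(beta_grid, "beta")
  stopifnot(inherits(net, "assoc_network"))
  sm_norm <- normalize_columns(sm)
  sp_norm <- normalize_columns(sp)
  mtil <- lapply(alpha_grid, function(a) relevance_basis(sm_norm, a))
  ptil <- lapply(beta_grid, function(b) relevance_basis(sp_norm, b))
  grid_df <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                         KEEP.OUT.ATTRS = FALSE)
  ai <- match(grid_df$alpha, alpha_grid)
  bi <- match(grid_df$beta, beta_grid)

  a_full <- net$adjacency
  n <- nrow(a_full); m <- ncol(a_full)
  deg <- rowSums(a_full)
  folds <- which(deg >= 1 & deg < m)   # need a held-out positive and a negative
  if (length(folds) == 0) stop_validation("no miRNA is usable as a validation fold")

  records <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    v <- folds[k]
    a_inner <- a_full
    a_inner[v, ] <- 0
    inner_queries <- setdiff(seq_len(n), v)
    inner_auc <- mapply(function(a_idx, b_idx) {
      netcbi_loocv_auc(mtil[[a_idx]], ptil[[b_idx]], a_inner, inner_queries)
    }, ai, bi)
    sel <- select_best(data.frame(alpha = grid_df$alpha, beta = grid_df$beta,
                                  auc = inner_auc))
    u <- a_inner %*% ptil[[match(sel$beta, beta_grid)]]
    val_scores <- cor_columns_vs(u, mtil[[match(sel$alpha, alpha_grid)]][, v])
    records[[k]] <- data.frame(
      fold_id = net$mirna_ids[v], alpha = sel$alpha, beta = sel$beta,
      inner_auc = sel$auc,
      validation_auc = auc_rank(val_scores, a_full[v, ] == 1))
  }
  per_fold <- do.call(rbind, records)
  rownames(per_fold) <- NULL

  full_auc <- mapply(function(a_idx, b_idx) {
    netcbi_loocv_auc(mtil[[a_idx]], ptil[[b_idx]], a_full)
  }, ai, bi)
  grid_df$auc <- full_auc
  structure(list(grid = grid_df,
                 selected = select_best(grid_df),
                 outer_auc = mean(per_fold$validation_auc),
                 selected_per_fold = per_fold),
            class = "tuning_result")
}
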
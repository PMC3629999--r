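#' Construct a bipartite miRNA-phenotype association network
#'
#' Wraps the binary n x m adjacency matrix `a` of the bipartite graph
#' G(M, P, E): rows are miRNAs, columns are disease phenotypes, and
#' `a[i, j] = 1` records a verified association between miRNA i and
#' phenotype j.
#'
#' @param adjacency Binary numeric matrix (entries exactly 0 or 1).
#' @param mirna_ids Character vector of miRNA identifiers (rows).
#' @param phenotype_ids Character vector of phenotype identifiers (columns).
#' @param dropped_edges Count of input edges discarded during loading.
#' @return An object of class `assoc_network`: a list with `mirna_ids`,
#'   `phenotype_ids`, `adjacency`, `n_edges` and `dropped_edges`.
#' @export
assoc_network <- function(adjacency, mirna_ids = rownames(adjacency),
                          phenotype_ids = colnames(adjacency),
                          dropped_edges = 0L) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (is.null(mirna_ids)) mirna_ids <- paste0("m", seq_len(nrow(adjacency)))
  if (is.null(phenotype_ids)) phenotype_ids <- paste0("p", seq_len(ncol(adjacency)))
  mirna_ids <- as.character(mirna_ids)
  phenotype_ids <- as.character(phenotype_ids)
  if (length(mirna_ids) != nrow(adjacency) ||
      length(phenotype_ids) != ncol(adjacency)) {
    stop_validation("ID vectors do not match adjacency dimensions")
  }
  if (anyDuplicated(mirna_ids) || anyDuplicated(phenotype_ids)) {
    stop_validation("duplicate IDs on an axis of the association network")
  }
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1))) {
    stop_validation("adjacency entries must be exactly 0 or 1")
  }
  dimnames(adjacency) <- list(mirna_ids, phenotype_ids)
  structure(list(mirna_ids = mirna_ids, phenotype_ids = phenotype_ids,
                 adjacency = adjacency, n_edges = sum(adjacency),
                 dropped_edges = as.integer(dropped_edges)),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network: %d miRNAs x %d phenotypes, %d associations",
              length(x$mirna_ids), length(x$phenotype_ids), x$n_edges))
  if (x$dropped_edges > 0) cat(sprintf(" (%d input edges dropped)", x$dropped_edges))
  cat("\n")
  invisible(x)
}

#' Load an association edge list against fixed ID universes
#'
#' Reads a two-column TSV of (miRNA ID, phenotype ID) pairs and builds the
#' binary adjacency over the supplied ID universes (normally the ID sets of
#' the two similarity matrices). Edges naming a miRNA absent from
#' `mirna_universe` are dropped and counted -- the same filter that reduces
#' a raw association catalogue to the subset covered by the miRNA
#' similarity resource. Edges naming an unknown phenotype are dropped with
#' a warning by default, or raise an error when `on_unknown_phenotype =
#' "fail"`.
#'
#' @param path Two-column TSV (optionally gzipped); a header line whose
#'   first field does not appear in either universe is skipped.
#' @param mirna_universe,phenotype_universe Character vectors of admissible IDs.
#' @param on_unknown_phenotype `"drop"` (default) or `"fail"`.
#' @return An [assoc_network()] over the full universes; `dropped_edges`
#'   counts discarded input lines, and duplicated edges collapse to a
#'   single association.
#' @export
load_associations <- function(path, mirna_universe, phenotype_universe,
                              on_unknown_phenotype = c("drop", "fail")) {
  on_unknown_phenotype <- match.arg(on_unknown_phenotype)
  if (!file.exists(path)) stop_format("edge-list file not found: %s", path)
  mirna_universe <- as.character(mirna_universe)
  phenotype_universe <- as.character(phenotype_universe)
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame(V1 = character(0), V2 = character(0))
      } else {
        stop_format("cannot parse edge list %s: %s", path, conditionMessage(e))
      }
    })
  if (nrow(df) > 0 && ncol(df) < 2) {
    stop_format("edge list %s must have two tab-separated columns", path)
  }
  adjacency <- matrix(0, length(mirna_universe), length(phenotype_universe),
                      dimnames = list(mirna_universe, phenotype_universe))
  dropped <- 0L
  if (nrow(df) > 0) {
    mir <- df[[1]]; phe <- df[[2]]
    # tolerate a header line: both fields unknown to their universes
    if (!(mir[1] %in% mirna_universe) && !(phe[1] %in% phenotype_universe) &&
        nrow(df) > 1) {
      mir <- mir[-1]; phe <- phe[-1]
    }
    bad_ph <- (mir %in% mirna_universe) & !(phe %in% phenotype_universe)
    if (any(bad_ph)) {
      if (on_unknown_phenotype == "fail") {
        stop_validation("edge list references unknown phenotype(s): %s",
                        paste(unique(phe[bad_ph]), collapse = ", "))
      }
      warning(sprintf("%d edge(s) dropped: unknown phenotype ID(s) %s",
                      sum(bad_ph), paste(unique(phe[bad_ph]), collapse = ", ")))
    }
    keep <- (mir %in% mirna_universe) & (phe %in% phenotype_universe)
    dropped <- sum(!keep)
    adjacency[cbind(mir[keep], phe[keep])] <- 1
  }
  assoc_network(adjacency, mirna_universe, phenotype_universe,
                dropped_edges = dropped)
}

#' Write an association network as a two-column edge list TSV
#'
#' @param net An [assoc_network()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_associations <- function(net, path) {
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(mirna = net$mirna_ids[idx[, 1]],
                   phenotype = net$phenotype_ids[idx[, 2]])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Degree statistics of the association network
#'
#' Node counts, edge count, average degree on each side and the two degree
#' sequences -- the summary a first look at a bipartite association
#' catalogue reports.
#'
#' @param net An [assoc_network()].
#' @return A list with `n_mirnas`, `n_phenotypes`, `n_edges`,
#'   `avg_mirna_degree` (edges / n), `avg_phenotype_degree` (edges / m),
#'   and the named degree vectors `mirna_degrees`, `phenotype_degrees`.
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  dm <- rowSums(net$adjacency)
  dp <- colSums(net$adjacency)
  list(n_mirnas = length(net$mirna_ids),
       n_phenotypes = length(net$phenotype_ids),
       n_edges = sum(net$adjacency),
       avg_mirna_degree = sum(net$adjacency) / length(net$mirna_ids),
       avg_phenotype_degree = sum(net$adjacency) / length(net$phenotype_ids),
       mirna_degrees = dm,
       phenotype_degrees = dp)
}

#' Single-entity query indicator
#'
#' The binary query vector of the relevance propagation: all zeros except a
#' one at the query entity (several ones are allowed for multi-entity
#' queries to [laplacian_relevance()]).
#'
#' @param axis `"mirna"` or `"phenotype"`.
#' @param ids Full ID vector of that axis.
#' @param query IDs (or integer positions) of the query entities.
#' @return An object of class `query_indicator` with the 0/1 vector in
#'   `$vector`, named by `ids`.
#' @export
query_indicator <- function(axis = c("mirna", "phenotype"), ids, query) {
  axis <- match.arg(axis)
  ids <- as.character(ids)
  v <- numeric(length(ids))
  names(v) <- ids
  idx <- if (is.numeric(query)) as.integer(query) else match(as.character(query), ids)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(ids))) {
    stop_validation("query entity not found on the %s axis", axis)
  }
  if (length(idx) == 0L) stop_validation("query must name at least one entity")
  v[idx] <- 1
  structure(list(axis = axis, index = idx, vector = v),
            class = "query_indicator")
}
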
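#' Construct a similarity matrix object
#'
#' A `similarity_matrix` wraps a square, non-negative matrix of pairwise
#' similarity scores together with its entity identifiers (miRNA names or
#' OMIM phenotype IDs) and a flag recording whether its columns have been
#' normalized to sum to one.
#'
#' @param values Square numeric matrix of non-negative similarities.
#' @param ids Character vector of entity identifiers, one per row/column.
#'   Defaults to the row names of `values`.
#' @param normalized Logical; `TRUE` if columns already sum to one.
#' @return An object of class `similarity_matrix`: a list with elements
#'   `ids`, `values` (with `ids` as dimnames) and `normalized`.
#' @examples
#' m <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' similarity_matrix(m)
#' @export
similarity_matrix <- function(values, ids = rownames(values), normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_format("similarity matrix must be square, got %d x %d",
                nrow(values), ncol(values))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) {
    stop_validation("length of ids (%d) does not match matrix dimension (%d)",
                    length(ids), nrow(values))
  }
  if (anyDuplicated(ids)) {
    stop_validation("duplicate entity IDs: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) stop_validation("similarity matrix contains missing values")
  if (any(values < 0)) stop_validation("similarity matrix contains negative entries")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, normalized = isTRUE(normalized)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d entities%s\n", length(x$ids),
              if (x$normalized) " (column-normalized)" else ""))
  cat("ids:", paste(utils::head(x$ids, 5), collapse = ", "),
      if (length(x$ids) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.similarity_matrix <- function(x) dim(x$values)

#' Load a similarity matrix from a TSV file
#'
#' Reads a tab-separated table whose first row holds column IDs and whose
#' first column holds row IDs (the dialect written by [write_similarity()]).
#' Gzip-compressed files are read transparently. Row and column IDs must
#' agree; asymmetry of the values beyond `1e-8` is reported as a warning
#' (column normalization breaks symmetry anyway, so it is not an error).
#'
#' @param path Path to a TSV (optionally `.gz`) file.
#' @return An un-normalized [similarity_matrix()].
#' @export
load_similarity <- function(path) {
  if (!file.exists(path)) stop_format("similarity file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop_format("similarity table in %s is not square (%d rows, %d columns)",
                path, nrow(m), ncol(m))
  }
  if (!is.numeric(m)) stop_format("non-numeric cells in similarity table %s", path)
  if (!identical(rownames(m), colnames(m))) {
    stop_format("row IDs and column IDs differ in %s", path)
  }
  s <- similarity_matrix(m, ids = rownames(m), normalized = FALSE)
  asym <- max(abs(s$values - t(s$values)))
  if (asym > 1e-8) {
    warning(sprintf("similarity matrix %s is asymmetric (max |S - t(S)| = %.3g); using values as given",
                    path, asym))
  }
  s
}

#' Write a similarity matrix as TSV
#'
#' @param s A [similarity_matrix()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(s, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(s$values, trim = TRUE, digits = 15, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Normalize similarity-matrix columns to sum to one
#'
#' Divides every column by its own sum, producing the column-stochastic
#' operator used by the graph-Laplacian relevance propagation. Columns whose
#' sum is zero carry no information and are left as all-zero vectors. The
#' input object is not modified. Applying the function to an
#' already-normalized matrix warns and returns it unchanged (the operation
#' is idempotent).
#'
#' @param s A [similarity_matrix()].
#' @return A column-normalized [similarity_matrix()].
#' @examples
#' s <- similarity_matrix(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
#' colSums(normalize_columns(s)$values)
#' @export
normalize_columns <- function(s) {
  stopifnot(inherits(s, "similarity_matrix"))
  if (s$normalized) {
    warning("similarity matrix is already column-normalized; returning it unchanged")
    return(s)
  }
  cs <- colSums(s$values)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  out <- sweep(s$values, 2, scale, `*`)
  similarity_matrix(out, ids = s$ids, normalized = TRUE)
}
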
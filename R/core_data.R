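#' @keywords internal
"_PACKAGE"

# Shared validation tolerance for adjacency axioms.
.ADJ_TOL <- 1e-12

#' Validate a gene expression matrix
#'
#' Checks the conventions used throughout the package: genes are rows, samples
#' are columns, both carry unique identifiers, no entry is missing, and the
#' matrix is large enough for pairwise association measures (at least 2 genes
#' and 3 samples).
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   row and column names.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (nrow(values) < 2) stop("need at least 2 genes, got ", nrow(values))
  if (ncol(values) < 3) stop("need at least 3 samples, got ", ncol(values))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at gene '", rownames(values)[idx[1]],
         "', sample '", colnames(values)[idx[2]],
         "' (missing values are rejected; no estimator here defines their handling)")
  }
  values
}

#' Read a delimited gene expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; every remaining cell must parse as a number. The file is
#' validated with [validate_expression()] (strict missing-value policy) and
#' row/column order is preserved.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator, default tab.
#' @return Numeric matrix with gene ids as rownames and sample ids as colnames.
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("input format error in ", path,
                          ": expected gene ids plus at least one sample column")
  gene_ids <- as.character(raw[[1]])
  num <- raw[-1]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(parsed) & !is.na(col))
      if (length(bad))
        stop("input format error in ", path, ": cell at line ", bad[1] + 1L,
             ", column ", j + 1L, " ('", col[bad[1]], "') is not a number")
      num[[j]] <- parsed
    }
  }
  values <- as.matrix(num)
  rownames(values) <- gene_ids
  validate_expression(values)
}

#' Write a square (association or adjacency) matrix as delimited text
#'
#' Identifiers are written as both the header row and the first column, so a
#' read-back with [read_matrix()] reproduces the values to 1e-12.
#'
#' @param mat Square numeric matrix with identical row and column names and at
#'   least 2 rows.
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @export
write_matrix <- function(mat, path, delimiter = "\t") {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("expected a square matrix")
  if (nrow(mat) < 2) stop("matrix must have at least 2 rows")
  if (is.null(rownames(mat))) stop("matrix must carry ids as dimnames")
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a square matrix written by [write_matrix()]
#'
#' @inheritParams read_expression
#' @return Square numeric matrix with ids as dimnames.
#' @export
read_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  ids <- as.character(raw[[1]])
  values <- as.matrix(raw[-1])
  rownames(values) <- ids
  if (nrow(values) != ncol(values))
    stop("input format error: matrix in ", path, " is not square")
  storage.mode(values) <- "double"
  values
}

#' Validate the adjacency axioms
#'
#' An adjacency matrix must have all entries in \[0, 1\], be symmetric, and have
#' a unit diagonal. All three axioms are checked to a tolerance of 1e-12; on
#' success the diagonal is forced to exactly 1.
#'
#' @param values Square numeric matrix.
#' @param tol Numerical tolerance for the axioms.
#' @return The matrix with diagonal set to exactly 1.
#' @export
validate_adjacency <- function(values, tol = .ADJ_TOL) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("adjacency must be a square matrix")
  lo <- min(values); hi <- max(values)
  if (lo < -tol || hi > 1 + tol) {
    idx <- which(values == (if (lo < -tol) lo else hi), arr.ind = TRUE)[1, ]
    stop("range axiom violated: entry (", idx[1], ",", idx[2], ") = ",
         format(values[idx[1], idx[2]]), " is outside [0,1]")
  }
  asym <- abs(values - t(values))
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("symmetry axiom violated: |A[", idx[1], ",", idx[2], "] - A[",
         idx[2], ",", idx[1], "]| = ", format(max(asym)))
  }
  if (max(abs(diag(values) - 1)) > tol) {
    i <- which.max(abs(diag(values) - 1))
    stop("unit-diagonal axiom violated: A[", i, ",", i, "] = ",
         format(values[i, i]))
  }
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  values
}

#' Relabel a module partition into canonical form
#'
#' Nonzero labels are renumbered 1..K in decreasing order of module size
#' (ties by first appearance); 0 stays 0 (unassigned/background).
#'
#' @param labels Integer vector of module labels, 0 = unassigned.
#' @return Integer vector with contiguous nonzero labels.
#' @export
canonical_partition <- function(labels) {
  labels <- as.integer(labels)
  if (any(labels < 0)) stop("module labels must be non-negative integers")
  nz <- labels[labels != 0]
  if (!length(nz)) return(labels)
  sizes <- table(nz)
  ord <- names(sizes)[order(-sizes, as.integer(names(sizes)))]
  out <- integer(length(labels))
  for (k in seq_along(ord)) out[labels == as.integer(ord[k])] <- k
  names(out) <- names(labels)
  out
}

#' Write an edge list for a symmetric matrix
#'
#' Upper-triangle entries with weight above `threshold` are written as a TSV
#' with columns `id_a`, `id_b`, `weight`. Useful for sparse outputs of the
#' network inference algorithms.
#'
#' @param mat Square symmetric matrix with ids as dimnames.
#' @param path Output path.
#' @param threshold Minimum weight for an edge to be written (default 0,
#'   strictly greater).
#' @export
write_edge_list <- function(mat, path, threshold = 0) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) stop("expected a square matrix")
  ids <- rownames(mat)
  ut <- which(upper.tri(mat) & mat > threshold, arr.ind = TRUE)
  df <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                   weight = mat[ut], stringsAsFactors = FALSE)
  df <- df[order(df$id_a, df$id_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Internal: check a square association-type matrix and matching ids.
.check_square <- function(S, what = "association matrix") {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop(what, " must be a square matrix")
  S
}
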
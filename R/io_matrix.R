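#' Construct an annotated expression matrix
#'
#' Bundles a nonnegative cells x genes matrix with cell and gene identifiers
#' and a cell-level metadata table. This is the container every other
#' function in the package operates on. Values may be raw counts or
#' library-normalized expression; the entropy machinery treats them as
#' nonnegative weights, so either is accepted (results differ between the
#' two and the choice should be reported alongside any scores).
#'
#' @param values numeric matrix or sparse \code{Matrix}, cells in rows and
#'   genes in columns, all entries >= 0. Stored internally as
#'   column-compressed sparse (\code{dgCMatrix}) so per-gene slicing is cheap.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_ids character vector of unique gene identifiers, one per column.
#' @param cell_metadata data.frame with one row per cell; its first column
#'   (or row names) must contain every cell id exactly once. Additional
#'   columns are categorical annotations (tissue, sex, strain, sample id, ...).
#' @return An object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, cell_ids, gene_ids, cell_metadata) {
  if (!inherits(values, "Matrix")) {
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  }
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("dimension mismatch: matrix is ", nrow(values), " x ", ncol(values),
         " but ", length(cell_ids), " cell ids and ",
         length(gene_ids), " gene ids were supplied", call. = FALSE)
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(cell_ids)) stop("cell ids are not unique", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene ids are not unique", call. = FALSE)
  if (length(values@x) && min(values@x) < 0) {
    stop("expression values must be nonnegative", call. = FALSE)
  }
  cell_metadata <- as.data.frame(cell_metadata, stringsAsFactors = FALSE)
  meta_ids <- if (!is.null(rownames(cell_metadata)) &&
                  !identical(rownames(cell_metadata),
                             as.character(seq_len(nrow(cell_metadata))))) {
    rownames(cell_metadata)
  } else {
    as.character(cell_metadata[[1L]])
  }
  if (anyDuplicated(meta_ids)) {
    stop("cell metadata contains duplicated cell ids", call. = FALSE)
  }
  missing <- setdiff(cell_ids, meta_ids)
  if (length(missing)) {
    stop("cell metadata is missing cell ids: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cell_metadata <- cell_metadata[match(cell_ids, meta_ids), , drop = FALSE]
  rownames(cell_metadata) <- cell_ids
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         cell_metadata = cell_metadata),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$cell_ids), "cells x",
      length(x$gene_ids), "genes\n")
  cat("metadata columns:",
      paste(colnames(x$cell_metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from Matrix Market + TSV sidecars
#'
#' Reads the standard sparse-matrix exchange layout: a Matrix Market
#' coordinate file, one-identifier-per-line gene and cell files, and a
#' header-bearing metadata TSV whose first column holds cell identifiers.
#' Orientation is auto-resolved so that rows are cells: if the stored
#' dimensions match genes x cells instead, the matrix is transposed.
#'
#' @param matrix_path path to the \code{.mtx} file (coordinate format).
#' @param genes_path path to gene identifiers, one per line.
#' @param cells_path path to cell identifiers, one per line.
#' @param metadata_path path to a tab-separated metadata table with a header;
#'   first column must match the cell identifiers.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_matrix <- function(matrix_path, genes_path, cells_path, metadata_path) {
  mm <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  cells <- readLines(cells_path)
  cells <- cells[nzchar(cells)]
  if (nrow(mm) == length(cells) && ncol(mm) == length(genes)) {
    # rows already cells
  } else if (nrow(mm) == length(genes) && ncol(mm) == length(cells)) {
    mm <- Matrix::t(mm)
  } else {
    stop("matrix dimensions ", nrow(mm), " x ", ncol(mm),
         " match neither cells x genes (", length(cells), " x ",
         length(genes), ") nor genes x cells", call. = FALSE)
  }
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = "character",
                            check.names = FALSE)
  expression_matrix(mm, cells, genes, meta)
}

#' Remove genes expressed in too few cells
#'
#' A gene counts as expressed in a cell when its value is strictly positive.
#' Genes expressed in fewer than \code{min_cells} cells are removed; ties at
#' the threshold are retained. The cell set is unchanged.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param min_cells minimum number of expressing cells a gene must have
#'   (default 100).
#' @param verbose report the number of genes removed (default TRUE).
#' @return A filtered \code{ExpressionMatrix} with attribute
#'   \code{n_removed}.
#' @export
filter_genes <- function(m, min_cells = 100, verbose = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"), min_cells >= 1)
  n_expressing <- Matrix::colSums(m$values > 0)
  keep <- n_expressing >= min_cells
  if (!any(keep)) {
    stop("all ", length(keep), " genes are expressed in fewer than ",
         min_cells, " cells; lower min_cells", call. = FALSE)
  }
  n_removed <- sum(!keep)
  if (verbose && n_removed > 0) {
    message("filter_genes: removed ", n_removed, " of ", length(keep),
            " genes expressed in fewer than ", min_cells, " cells")
  }
  out <- expression_matrix(m$values[, keep, drop = FALSE], m$cell_ids,
                           m$gene_ids[keep], m$cell_metadata)
  attr(out, "n_removed") <- n_removed
  out
}

#' Write an expression matrix as Matrix Market + TSV sidecars
#'
#' Inverse of \code{\link{read_matrix}}; writes \code{matrix.mtx},
#' \code{genes.tsv}, \code{cells.tsv} and \code{metadata.tsv} under
#' \code{dir}.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param dir output directory, created if needed.
#' @return Invisibly, the four paths written.
#' @export
write_matrix <- function(m, dir) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv",
                            "metadata.tsv"))
  mm <- m$values
  dimnames(mm) <- NULL
  Matrix::writeMM(mm, paths[1L])
  writeLines(m$gene_ids, paths[2L])
  writeLines(m$cell_ids, paths[3L])
  meta <- cbind(cell_id = m$cell_ids,
                m$cell_metadata[setdiff(colnames(m$cell_metadata), "cell_id")])
  utils::write.table(meta, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write aggregated specificity scores to TSV
#'
#' One row per gene per partition. Columns: \code{gene}, \code{partition},
#' \code{Psi_mean}, \code{Psi_sd}, \code{zeta_mean}, \code{zeta_sd}, one
#' \code{psi_<block>} column per block (Aitchison mean) each followed by its
#' \code{psi_<block>_gsd}, then any p-value and q-value columns present.
#' Block columns follow the partition's block order. Values are written with
#' enough digits to round-trip (\code{format(..., digits = 15)}).
#'
#' @param scores data.frame of aggregated scores (see
#'   \code{\link{aggregate_draws}}).
#' @param out_path output file path.
#' @return Invisibly, \code{out_path}.
#' @export
write_scores <- function(scores, out_path) {
  stopifnot(is.data.frame(scores))
  df <- scores
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "NA", format(v, digits = 15, scientific = FALSE,
                                  trim = TRUE))
  })
  utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(out_path)
}

#' Read a score table written by \code{write_scores}
#' @param path path to the TSV.
#' @return data.frame with numeric score columns.
#' @export
read_scores <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
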
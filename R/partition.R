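#' Construct a partition of cells into labeled blocks
#'
#' A partition assigns every cell to exactly one of r named blocks. Block
#' label order is explicit and stable: it fixes output column order and
#' polygon vertex order downstream.
#'
#' @param assignment integer vector, one entry per cell, giving the block
#'   index (1-based) of each cell; or a character/factor vector of block
#'   labels.
#' @param block_labels character vector of unique block labels. Required
#'   when \code{assignment} is integer; optional otherwise (defaults to the
#'   sorted unique labels).
#' @param name partition name, e.g. \code{"tissue"} or
#'   \code{"sex:strain:tissue"}.
#' @return An object of class \code{Partition} with fields \code{name},
#'   \code{block_labels} and integer \code{assignment}.
#' @export
partition <- function(assignment, block_labels = NULL, name = "partition") {
  if (is.factor(assignment)) assignment <- as.character(assignment)
  if (is.character(assignment)) {
    if (is.null(block_labels)) block_labels <- sort(unique(assignment))
    idx <- match(assignment, block_labels)
    if (anyNA(idx)) {
      stop("assignment contains labels absent from block_labels: ",
           paste(unique(assignment[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    assignment <- idx
  } else {
    assignment <- as.integer(assignment)
    if (is.null(block_labels)) {
      stop("block_labels required for integer assignments", call. = FALSE)
    }
  }
  block_labels <- as.character(block_labels)
  if (anyDuplicated(block_labels)) {
    stop("block labels are not unique", call. = FALSE)
  }
  r <- length(block_labels)
  if (anyNA(assignment) || any(assignment < 1L) || any(assignment > r)) {
    stop("every cell must be assigned to exactly one block", call. = FALSE)
  }
  counts <- tabulate(assignment, nbins = r)
  if (any(counts == 0L)) {
    stop("empty blocks are not allowed: ",
         paste(block_labels[counts == 0L], collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, block_labels = block_labels,
                 assignment = assignment),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat("Partition \"", x$name, "\": ", length(x$assignment), " cells in ",
      length(x$block_labels), " blocks\n", sep = "")
  print(stats::setNames(tabulate(x$assignment,
                                 nbins = length(x$block_labels)),
                        x$block_labels))
  invisible(x)
}

#' Number of blocks of a partition
#' @param p a \code{Partition}.
#' @return integer r.
#' @export
n_blocks <- function(p) length(p$block_labels)

#' Build a partition from metadata columns
#'
#' One block per observed combination of the named categorical columns,
#' labeled by joining values with \code{":"} in the given column order
#' (mirroring interaction-term notation such as \code{sex:strain:tissue}).
#' Combinations with zero cells are omitted. Blocks are ordered
#' lexicographically by label unless \code{block_order} is supplied.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param columns character vector of metadata column names; with more than
#'   one column the partition is their interaction.
#' @param block_order optional explicit block label ordering (a permutation
#'   of the observed labels), e.g. a biologically meaningful vertex order
#'   for polygon plots.
#' @return A \code{Partition} over the cells of \code{m}.
#' @export
partition_from_metadata <- function(m, columns, block_order = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), length(columns) >= 1L)
  missing_cols <- setdiff(columns, colnames(m$cell_metadata))
  if (length(missing_cols)) {
    stop("metadata column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(columns, function(cn) as.character(m$cell_metadata[[cn]]))
  na_cells <- Reduce(`|`, lapply(cols, is.na))
  if (any(na_cells)) {
    stop("missing values in partition columns for cells: ",
         paste(utils::head(m$cell_ids[na_cells], 10L), collapse = ", "),
         call. = FALSE)
  }
  labels <- do.call(paste, c(cols, sep = ":"))
  observed <- sort(unique(labels))
  if (length(observed) < 2L) {
    stop("partition must have at least 2 blocks; column(s) ",
         paste(columns, collapse = ":"), " yield ", length(observed),
         call. = FALSE)
  }
  if (!is.null(block_order)) {
    if (!setequal(block_order, observed) ||
        length(block_order) != length(observed)) {
      stop("block_order must be a permutation of the observed labels",
           call. = FALSE)
    }
    observed <- block_order
  }
  partition(labels, block_labels = observed,
            name = paste(columns, collapse = ":"))
}

#' Test whether one partition refines another
#'
#' \code{fine} refines \code{coarse} when every fine block lies wholly
#' inside one coarse block. Refinement underlies the grouping property of
#' the between-block entropy: the fine between entropy equals the coarse
#' between entropy plus the mass-weighted between entropies within each
#' coarse block.
#'
#' @param fine,coarse \code{Partition}s over the same cells.
#' @return logical.
#' @export
is_refinement <- function(fine, coarse) {
  stopifnot(inherits(fine, "Partition"), inherits(coarse, "Partition"))
  if (length(fine$assignment) != length(coarse$assignment)) {
    stop("partitions cover different numbers of cells", call. = FALSE)
  }
  # each fine block must map to a single coarse block
  all(tapply(coarse$assignment, fine$assignment,
             function(v) length(unique(v)) == 1L))
}

#' Restrict a partition to a subset of cells
#'
#' Blocks emptied by the restriction are dropped from the label list with a
#' warning; the surviving labels keep their relative order.
#'
#' @param p a \code{Partition}.
#' @param cells integer indices (into the original cell order) to keep.
#' @return A \code{Partition} over the subset.
#' @export
restrict_partition <- function(p, cells) {
  stopifnot(inherits(p, "Partition"), length(cells) >= 1L)
  sub <- p$assignment[cells]
  present <- sort(unique(sub))
  if (length(present) < 2L) {
    stop("restriction leaves fewer than 2 nonempty blocks (degenerate ",
         "partition)", call. = FALSE)
  }
  dropped <- setdiff(seq_along(p$block_labels), present)
  if (length(dropped)) {
    warning("restriction dropped empty block(s): ",
            paste(p$block_labels[dropped], collapse = ", "), call. = FALSE)
  }
  partition(match(sub, present), block_labels = p$block_labels[present],
            name = p$name)
}
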
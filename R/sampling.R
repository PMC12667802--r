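#' Balanced sampling design over biological replicates
#'
#' Describes how samples (biological replicates) are drawn so that every
#' experimental condition is represented exactly once per category in each
#' draw. "Category" and "condition" are user-designated roles over metadata
#' columns and can be used interchangeably; sampling operates on unique
#' sample identifiers, not individual cells.
#'
#' @param category_column metadata column naming the category (e.g. strain).
#' @param condition_column metadata column naming the condition (e.g. sex).
#' @param sample_id_column metadata column holding unique sample/replicate
#'   identifiers (e.g. mouse id).
#' @param n_draws number of balanced subsets to generate (default 100).
#' @param seed integer seed controlling tie-breaking.
#' @return A list of class \code{SamplingDesign}.
#' @export
sampling_design <- function(category_column, condition_column,
                            sample_id_column, n_draws = 100, seed = 1L) {
  stopifnot(n_draws >= 1)
  structure(list(category_column = category_column,
                 condition_column = condition_column,
                 sample_id_column = sample_id_column,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "SamplingDesign")
}

#' Generate balanced draws of sample identifiers
#'
#' Each draw contains exactly one sample id per (category, condition) pair.
#' Within a pair, the least-used eligible sample (usage tracked across all
#' draws so far) is selected; ties are broken by a seeded RNG stream, so the
#' draw sequence is reproducible for a fixed seed. Complete balance is
#' enforced: every pair observed in the metadata must have at least one
#' sample.
#'
#' @param metadata cell-level metadata table containing the design's three
#'   columns (each sample id must map to a single category and condition).
#' @param design a \code{\link{sampling_design}}.
#' @return List of length \code{n_draws}; each element a character vector of
#'   sample ids, one per (category, condition) pair.
#' @export
balanced_draws <- function(metadata, design) {
  stopifnot(inherits(design, "SamplingDesign"))
  need <- c(design$category_column, design$condition_column,
            design$sample_id_column)
  miss <- setdiff(need, colnames(metadata))
  if (length(miss)) {
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samp <- unique(data.frame(
    sample = as.character(metadata[[design$sample_id_column]]),
    category = as.character(metadata[[design$category_column]]),
    condition = as.character(metadata[[design$condition_column]]),
    stringsAsFactors = FALSE))
  if (anyDuplicated(samp$sample)) {
    bad <- samp$sample[duplicated(samp$sample)]
    stop("sample id(s) map to more than one category/condition: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  cats <- sort(unique(samp$category))
  conds <- sort(unique(samp$condition))
  pairs <- expand.grid(category = cats, condition = conds,
                       stringsAsFactors = FALSE)
  pool <- lapply(seq_len(nrow(pairs)), function(i) {
    sort(samp$sample[samp$category == pairs$category[i] &
                       samp$condition == pairs$condition[i]])
  })
  empty <- lengths(pool) == 0L
  if (any(empty)) {
    stop("complete balance requires at least one sample for every ",
         "category-condition pair; empty pair(s): ",
         paste(paste(pairs$category[empty], pairs$condition[empty],
                     sep = ":"), collapse = ", "), call. = FALSE)
  }
  usage <- stats::setNames(integer(nrow(samp)), samp$sample)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)
  draws <- vector("list", design$n_draws)
  for (d in seq_len(design$n_draws)) {
    picks <- character(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      cand <- pool[[i]]
      least <- cand[usage[cand] == min(usage[cand])]
      pick <- if (length(least) == 1L) least else least[sample.int(length(least), 1L)]
      usage[pick] <- usage[pick] + 1L
      picks[i] <- pick
    }
    draws[[d]] <- picks
  }
  draws
}

#' Score every gene on each balanced draw
#'
#' For each draw, cells are restricted to samples in the draw, the partition
#' is restricted accordingly, and \code{\link{score_matrix}} is run on the
#' restricted matrix. Draws whose restriction collapses the partition to a
#' single block are skipped with a warning; if more than half the draws are
#' skipped this is an error. Genes that lose all expression within a draw
#' are flagged degenerate for that draw only.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param p a \code{Partition} over the cells of \code{m}.
#' @param draws list of sample-id vectors from \code{\link{balanced_draws}}.
#' @param design the \code{\link{sampling_design}} (for the sample id
#'   column).
#' @return List of per-draw score data.frames (skipped draws are dropped);
#'   attribute \code{n_skipped} counts skipped draws.
#' @export
scores_over_draws <- function(m, p, draws, design) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(p, "Partition"))
  sid <- as.character(m$cell_metadata[[design$sample_id_column]])
  out <- vector("list", length(draws))
  skipped <- 0L
  for (k in seq_along(draws)) {
    cells <- which(sid %in% draws[[k]])
    sub_p <- tryCatch(suppressWarnings(restrict_partition(p, cells)),
                      error = function(e) NULL)
    if (is.null(sub_p) || length(cells) == 0L) {
      warning("draw ", k, " collapses the partition; skipped",
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    sub_m <- expression_matrix(m$values[cells, , drop = FALSE],
                               m$cell_ids[cells], m$gene_ids,
                               m$cell_metadata[cells, , drop = FALSE])
    out[[k]] <- score_matrix(sub_m, sub_p)
  }
  if (skipped > length(draws) / 2) {
    stop("more than half of the balanced draws (", skipped, "/",
         length(draws), ") collapse the partition", call. = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  attr(out, "n_skipped") <- skipped
  attr(out, "block_labels") <- p$block_labels
  out
}

#' Aitchison mean of a set of compositions
#'
#' Component-wise geometric mean renormalized to sum to one — the
#' composition-space central tendency. Zeros are handled by multiplicative
#' replacement before taking logs (Aitchison geometry is undefined at zero):
#' each zero component is replaced by delta = half the smallest nonzero
#' component observed across all rows, and each row is renormalized.
#'
#' @param comps numeric matrix, one composition per row (rows sum to 1).
#' @return list with \code{mean} (composition summing to 1), \code{gsd}
#'   (per-component geometric standard deviation, >= 1; exactly 1 for a
#'   single row) and \code{delta} (the zero-replacement value used, 0 when
#'   no zeros were present).
#' @export
aitchison_mean <- function(comps) {
  comps <- as.matrix(comps)
  stopifnot(all(comps >= 0), nrow(comps) >= 1L)
  delta <- 0
  if (any(comps == 0)) {
    nzmin <- min(comps[comps > 0])
    delta <- nzmin / 2
    comps[comps == 0] <- delta
    comps <- comps / rowSums(comps)
  }
  lg <- log(comps)
  gm <- exp(colMeans(lg))
  gsd <- if (nrow(comps) == 1L) rep(1, ncol(comps)) else {
    exp(apply(lg, 2L, stats::sd))
  }
  list(mean = gm / sum(gm), gsd = gsd, delta = delta)
}

#' Aggregate per-draw scores into replicate-robust summaries
#'
#' Psi and zeta get arithmetic means and (n-1)-denominator standard
#' deviations over usable draws (SD 0 for a single draw). The psi_block
#' composition is aggregated with the \code{\link{aitchison_mean}}; its
#' variability is summarized by the per-block geometric standard deviation.
#' A draw is usable for a gene unless the gene had zero total expression in
#' it; genes with no usable draw are dropped (recorded in attribute
#' \code{dropped_genes}).
#'
#' @param per_draw list of per-draw score tables from
#'   \code{\link{scores_over_draws}} (or \code{\link{score_matrix}}).
#' @return data.frame with one row per gene: \code{gene}, \code{Psi_mean},
#'   \code{Psi_sd}, \code{zeta_mean}, \code{zeta_sd}, one
#'   \code{psi_<block>} (Aitchison mean) and \code{psi_<block>_gsd} pair
#'   per block, and \code{n_draws_used}.
#' @export
aggregate_draws <- function(per_draw) {
  stopifnot(length(per_draw) >= 1L)
  blocks <- attr(per_draw, "block_labels")
  if (is.null(blocks)) blocks <- attr(per_draw[[1L]], "block_labels")
  psi_cols <- paste0("psi_", blocks)
  genes <- per_draw[[1L]]$gene
  nd <- length(per_draw)
  G <- length(genes)
  r <- length(blocks)
  Psi <- zeta <- matrix(NA_real_, nd, G)
  psi_arr <- array(NA_real_, c(nd, G, r))
  for (k in seq_len(nd)) {
    tab <- per_draw[[k]]
    idx <- match(genes, tab$gene)
    usable <- tab$degenerate[idx] != "zero_total"
    Psi[k, usable] <- tab$Psi[idx[usable]]
    zeta[k, usable] <- tab$zeta[idx[usable]]
    have <- intersect(psi_cols, colnames(tab))
    psi_arr[k, usable, match(have, psi_cols)] <-
      as.matrix(tab[idx[usable], have, drop = FALSE])
  }
  n_used <- colSums(!is.na(Psi))
  keep <- n_used >= 1L
  sd0 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= 1L) 0 else stats::sd(v)
  }
  out <- data.frame(
    gene = genes[keep],
    Psi_mean = colMeans(Psi, na.rm = TRUE)[keep],
    Psi_sd = apply(Psi, 2L, sd0)[keep],
    zeta_mean = colMeans(zeta, na.rm = TRUE)[keep],
    zeta_sd = apply(zeta, 2L, sd0)[keep],
    stringsAsFactors = FALSE)
  amean <- matrix(NA_real_, sum(keep), r)
  gsd <- matrix(NA_real_, sum(keep), r)
  for (gi in seq_along(which(keep))) {
    g <- which(keep)[gi]
    comp <- psi_arr[, g, , drop = FALSE]
    dim(comp) <- c(nd, r)
    complete <- stats::complete.cases(comp)
    if (!any(complete)) next
    ag <- aitchison_mean(comp[complete, , drop = FALSE])
    amean[gi, ] <- ag$mean
    gsd[gi, ] <- ag$gsd
  }
  for (j in seq_len(r)) {
    out[[psi_cols[j]]] <- amean[, j]
    out[[paste0(psi_cols[j], "_gsd")]] <- gsd[, j]
  }
  out$n_draws_used <- n_used[keep]
  rownames(out) <- NULL
  attr(out, "block_labels") <- blocks
  attr(out, "dropped_genes") <- genes[!keep]
  attr(out, "partition") <- attr(per_draw[[1L]], "partition")
  out
}
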
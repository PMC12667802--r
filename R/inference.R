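#' Permutation p-values for the specificity metrics
#'
#' Generates null distributions by scrambling block labels: each
#' permutation shuffles the cell-to-block assignment uniformly at random,
#' preserving block sizes, and recomputes the full statistic pipeline. When
#' balanced draws are supplied the null statistic is, like the observed
#' one, the mean over draws; otherwise it is the single-matrix score.
#' Empirical p-values use the add-one estimator
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (1 + n_{perm})}, which avoids
#' p = 0 and its degenerate FDR ranking; the raw proportion
#' \eqn{\#\{perm \ge obs\}/n_{perm}} is available with
#' \code{add_one = FALSE}. Tests are one-sided: large values of Psi, zeta
#' and psi_block are significant.
#'
#' A permutation in which a gene degenerates contributes a null value of 0
#' for that gene (counted as below the observed statistic unless the
#' observed value is also 0). Genes whose observed scores are missing get
#' missing p-values.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param p a \code{Partition} over the cells of \code{m}.
#' @param observed aggregated score table for the same matrix, partition
#'   and draws (from \code{\link{aggregate_draws}} or, without sampling, a
#'   \code{\link{score_matrix}} table).
#' @param n_permutations number of label scrambles (default 100; at least
#'   20 — below that the empirical resolution is useless).
#' @param seed integer seed for the permutation stream.
#' @param draws optional list of balanced draws; when supplied together
#'   with \code{design}, the null recomputes the mean-over-draws statistic.
#' @param design the \code{\link{sampling_design}} matching \code{draws}.
#' @param add_one use the add-one p-value estimator (default TRUE).
#' @return data.frame: \code{gene}, \code{p_Psi}, \code{p_zeta}, and one
#'   \code{p_psi_<block>} per block.
#' @export
permutation_pvalues <- function(m, p, observed, n_permutations = 100,
                                seed = 1L, draws = NULL, design = NULL,
                                add_one = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(p, "Partition"))
  if (n_permutations < 20) {
    stop("n_permutations must be at least 20", call. = FALSE)
  }
  use_sampling <- !is.null(draws)
  if (use_sampling && is.null(design)) {
    stop("design is required when draws are supplied", call. = FALSE)
  }
  blocks <- p$block_labels
  r <- length(blocks)
  psi_cols <- paste0("psi_", blocks)
  obs_psi_col <- if (all(psi_cols %in% colnames(observed))) psi_cols else {
    stop("observed table lacks psi_<block> columns", call. = FALSE)
  }
  genes <- observed$gene
  obs_Psi <- if ("Psi_mean" %in% colnames(observed)) observed$Psi_mean else observed$Psi
  obs_zeta <- if ("zeta_mean" %in% colnames(observed)) observed$zeta_mean else observed$zeta
  obs_psi <- as.matrix(observed[, obs_psi_col, drop = FALSE])

  n <- length(p$assignment)
  ge_Psi <- integer(length(genes))
  ge_zeta <- integer(length(genes))
  ge_psi <- matrix(0L, length(genes), r)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    perm <- partition(p$assignment[sample.int(n)], p$block_labels,
                      name = p$name)
    null_tab <- if (use_sampling) {
      per_draw <- suppressWarnings(
        scores_over_draws(m, perm, draws, design))
      aggregate_draws(per_draw)
    } else {
      score_matrix(m, perm)
    }
    idx <- match(genes, null_tab$gene)
    nP <- if (use_sampling) null_tab$Psi_mean[idx] else null_tab$Psi[idx]
    nZ <- if (use_sampling) null_tab$zeta_mean[idx] else null_tab$zeta[idx]
    have <- intersect(psi_cols, colnames(null_tab))
    nB <- matrix(0, length(genes), r)
    nB[, match(have, psi_cols)] <-
      as.matrix(null_tab[idx, have, drop = FALSE])
    nP[is.na(nP)] <- 0
    nZ[is.na(nZ)] <- 0
    nB[is.na(nB)] <- 0
    # tolerance absorbs float jitter so exact ties (and rescaled inputs)
    # compare consistently; all metrics have magnitude <= 1
    ge_Psi <- ge_Psi + (nP >= obs_Psi - 1e-12)
    ge_zeta <- ge_zeta + (nZ >= obs_zeta - 1e-12)
    ge_psi <- ge_psi + (nB >= obs_psi - 1e-12)
  }
  to_p <- function(k) {
    if (add_one) (1 + k) / (1 + n_permutations) else k / n_permutations
  }
  out <- data.frame(gene = genes,
                    p_Psi = ifelse(is.na(obs_Psi), NA_real_, to_p(ge_Psi)),
                    p_zeta = ifelse(is.na(obs_zeta), NA_real_, to_p(ge_zeta)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(r)) {
    out[[paste0("p_", psi_cols[j])]] <-
      ifelse(is.na(obs_psi[, j]), NA_real_, to_p(ge_psi[, j]))
  }
  rownames(out) <- NULL
  attr(out, "block_labels") <- blocks
  out
}

#' Benjamini-Hochberg q-values over a pooled p-value list
#'
#' Standard BH step-up adjustment. Missing p-values propagate as missing
#' q-values and do not count toward the number of tests.
#'
#' @param pvalues numeric vector of p-values in (0, 1], pooled globally
#'   across metrics, genes and partitions.
#' @return numeric vector of q-values aligned to the input.
#' @export
bh_qvalues <- function(pvalues) {
  q <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Attach globally pooled q-values to score tables
#'
#' Pools every p-value column (\code{p_Psi}, \code{p_zeta},
#' \code{p_psi_<block>}) across all supplied tables — i.e. across metrics
#' and partitions — applies one global BH correction, and writes matching
#' \code{q_*} columns back into each table.
#'
#' @param tables a single score data.frame with \code{p_*} columns, or a
#'   list of them (one per partition).
#' @return The input with added \code{q_*} columns (same shape: single
#'   data.frame in, single data.frame out).
#' @export
add_global_qvalues <- function(tables) {
  single <- is.data.frame(tables)
  if (single) tables <- list(tables)
  pcols <- lapply(tables, function(t) grep("^p_", colnames(t), value = TRUE))
  pooled <- unlist(lapply(seq_along(tables), function(i) {
    unlist(tables[[i]][pcols[[i]]], use.names = FALSE)
  }))
  qs <- bh_qvalues(pooled)
  pos <- 0L
  for (i in seq_along(tables)) {
    for (cn in pcols[[i]]) {
      k <- nrow(tables[[i]])
      tables[[i]][[sub("^p_", "q_", cn)]] <- qs[pos + seq_len(k)]
      pos <- pos + k
    }
  }
  if (single) tables[[1L]] else tables
}
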
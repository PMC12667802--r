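#' Shannon entropy decomposition of one gene over a partition
#'
#' Treats the nonnegative expression vector as a probability distribution
#' over cells (p_i = x_i / sum(x)) and decomposes its Shannon entropy over
#' the blocks of a partition:
#' \deqn{E_T = E_B + E_W,\qquad E_W = \sum_C p_C E_C,}
#' where p_C is the fraction of the gene's total expression found in block
#' C, E_C is the entropy of the within-block distribution q_j = x_j /
#' sum_{k in C} x_k, and E_B is the between-block entropy
#' \eqn{-\sum_C p_C \log p_C}. Natural logarithms throughout; all reported
#' specificity metrics are base-invariant ratios. The convention
#' 0 log 0 := 0 applies everywhere, so empty or zero-mass blocks
#' contribute nothing.
#'
#' E_B is computed as E_T - E_W so the decomposition identity holds to
#' machine precision; the direct form agrees to numerical tolerance.
#'
#' @param x nonnegative numeric vector, one entry per cell.
#' @param p a \code{\link{partition}} covering the cells of \code{x}.
#' @return A list of class \code{EntropyDecomposition}: \code{E_T},
#'   \code{E_B}, \code{E_W} (nats), vectors \code{p_C} (block mass
#'   fractions, sum 1) and \code{E_C} (within-block entropies), and
#'   \code{block_labels}.
#' @export
decompose_entropy <- function(x, p) {
  stopifnot(inherits(p, "Partition"))
  x <- as.numeric(x)
  if (length(x) != length(p$assignment)) {
    stop("expression vector and partition cover different cell counts",
         call. = FALSE)
  }
  if (any(x < 0)) stop("expression values must be nonnegative", call. = FALSE)
  S <- sum(x)
  if (S == 0) stop("zero total expression; filter such genes upstream",
                   call. = FALSE)
  r <- n_blocks(p)
  xl <- numeric(length(x))
  nz <- x > 0
  xl[nz] <- x[nz] * log(x[nz])
  E_T <- log(S) - sum(xl) / S
  # rowsum drops absent groups; partitions forbid empty blocks so lengths match
  S_C <- as.numeric(rowsum(x, p$assignment, reorder = TRUE))
  xlx_C <- as.numeric(rowsum(xl, p$assignment, reorder = TRUE))
  E_C <- ifelse(S_C > 0, log(pmax(S_C, 1e-300)) - xlx_C / pmax(S_C, 1e-300), 0)
  E_C <- pmax(E_C, 0)
  p_C <- S_C / S
  E_W <- sum(p_C * E_C)
  E_T <- max(E_T, 0)
  structure(list(E_T = E_T, E_B = max(E_T - E_W, 0), E_W = E_W,
                 p_C = p_C, E_C = E_C, block_labels = p$block_labels),
            class = "EntropyDecomposition")
}

#' Specificity metrics from an entropy decomposition
#'
#' Converts a per-gene entropy decomposition into the three ratio metrics:
#' \itemize{
#'   \item \code{Psi} = E_W / E_T, the fraction of the gene's expression
#'     information explained by the partition (1 - E_B / E_T);
#'   \item \code{psi_blocks}, the compositional share of within-block
#'     information carried by each block, p_C E_C / E_W — a probability
#'     vector over blocks summing to one;
#'   \item \code{zeta} = 1 - H(psi_blocks) / log r, the normalized
#'     Kullback-Leibler divergence of the psi_block composition from the
#'     uniform distribution over the r blocks.
#' }
#' The block shares are mass-weighted (p_C E_C / E_W rather than the bare
#' ratio E_C / E_W) because E_W = sum_C p_C E_C: only the weighted form
#' yields a composition that sums to one, as the downstream Aitchison
#' aggregation and the zeta definition require.
#'
#' Degenerate cases: if E_T = 0 (at most one expressing cell) all scores
#' are NA with \code{degenerate_flag = "zero_total"}. If E_T > 0 but
#' E_W = 0 (no block holds two expressing cells) Psi = 0, the block
#' composition falls back to the mass fractions p_C, zeta is computed from
#' that composition, and \code{degenerate_flag = "zero_within"}.
#'
#' @param d an \code{EntropyDecomposition}.
#' @return A list of class \code{SpecificityScores}: \code{Psi},
#'   \code{zeta}, \code{psi_blocks} (named by block), and
#'   \code{degenerate_flag} in \code{c("none", "zero_total", "zero_within")}.
#' @export
specificity_scores <- function(d) {
  stopifnot(inherits(d, "EntropyDecomposition"))
  r <- length(d$block_labels)
  nm <- d$block_labels
  if (d$E_T == 0) {
    return(structure(list(Psi = NA_real_, zeta = NA_real_,
                          psi_blocks = stats::setNames(rep(NA_real_, r), nm),
                          degenerate_flag = "zero_total"),
                     class = "SpecificityScores"))
  }
  if (d$E_W == 0) {
    psi <- stats::setNames(d$p_C, nm)
    return(structure(list(Psi = 0, zeta = .zeta_from_composition(psi, r),
                          psi_blocks = psi,
                          degenerate_flag = "zero_within"),
                     class = "SpecificityScores"))
  }
  Psi <- min(max(d$E_W / d$E_T, 0), 1)
  psi <- stats::setNames(d$p_C * d$E_C / d$E_W, nm)
  psi <- psi / sum(psi)
  structure(list(Psi = Psi, zeta = .zeta_from_composition(psi, r),
                 psi_blocks = psi, degenerate_flag = "none"),
            class = "SpecificityScores")
}

.zeta_from_composition <- function(psi, r) {
  pos <- psi[psi > 0]
  H <- -sum(pos * log(pos))
  min(max(1 - H / log(r), 0), 1)
}

#' Specificity scores for every gene of a matrix
#'
#' Vectorized computation of the entropy decomposition and the three
#' specificity metrics for each gene under one partition. Per-gene results
#' match \code{\link{decompose_entropy}} followed by
#' \code{\link{specificity_scores}}; computation is shared across genes via
#' sparse block aggregation so large matrices stay fast.
#'
#' @param m an \code{ExpressionMatrix} (ideally pre-filtered with
#'   \code{\link{filter_genes}}).
#' @param p a \code{Partition} over the cells of \code{m}.
#' @return data.frame with one row per gene: \code{gene}, \code{E_T},
#'   \code{E_B}, \code{E_W}, \code{Psi}, \code{zeta}, one
#'   \code{psi_<block>} column per block (in partition block order) and
#'   \code{degenerate} flag. Genes with zero total expression carry NA
#'   scores and \code{degenerate = "zero_total"}; exclude them from
#'   ranking. Attribute \code{block_labels} records the block order.
#' @export
score_matrix <- function(m, p) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(p, "Partition"))
  X <- m$values
  if (nrow(X) != length(p$assignment)) {
    stop("matrix and partition cover different cell counts", call. = FALSE)
  }
  r <- n_blocks(p)
  G <- ncol(X)
  S <- Matrix::colSums(X)
  Xl <- X
  Xl@x <- X@x * log(X@x)
  T1 <- Matrix::colSums(Xl)
  # r x n indicator, so B %*% X aggregates cell rows into block rows
  B <- Matrix::sparseMatrix(i = p$assignment, j = seq_along(p$assignment),
                            x = 1, dims = c(r, nrow(X)))
  S_C <- as.matrix(B %*% X)      # r x G block totals
  L_C <- as.matrix(B %*% Xl)     # r x G block sum of x log x
  pos <- S <= 0
  E_T <- ifelse(pos, 0, log(pmax(S, 1e-300)) - T1 / pmax(S, 1e-300))
  E_T <- pmax(E_T, 0)
  E_Cm <- matrix(0, r, G)
  nz <- S_C > 0
  E_Cm[nz] <- log(S_C[nz]) - L_C[nz] / S_C[nz]
  E_Cm <- pmax(E_Cm, 0)
  p_Cm <- sweep(S_C, 2L, pmax(S, 1e-300), "/")
  W_Cm <- p_Cm * E_Cm            # per-block contribution to E_W
  E_W <- colSums(W_Cm)
  E_B <- pmax(E_T - E_W, 0)

  flag <- rep("none", G)
  flag[E_T == 0] <- "zero_total"
  flag[E_T > 0 & E_W == 0] <- "zero_within"

  Psi <- ifelse(E_T > 0, pmin(pmax(E_W / pmax(E_T, 1e-300), 0), 1), NA_real_)
  psi_m <- matrix(NA_real_, r, G)
  ok <- E_T > 0 & E_W > 0
  if (any(ok)) {
    psi_ok <- sweep(W_Cm[, ok, drop = FALSE], 2L, E_W[ok], "/")
    psi_m[, ok] <- sweep(psi_ok, 2L, colSums(psi_ok), "/")
  }
  zw <- flag == "zero_within"
  if (any(zw)) psi_m[, zw] <- p_Cm[, zw, drop = FALSE]
  zeta <- rep(NA_real_, G)
  comp_ok <- ok | zw
  if (any(comp_ok)) {
    pm <- psi_m[, comp_ok, drop = FALSE]
    plp <- ifelse(pm > 0, pm * log(pm), 0)
    zeta[comp_ok] <- pmin(pmax(1 + colSums(plp) / log(r), 0), 1)
  }
  out <- data.frame(gene = m$gene_ids, E_T = E_T, E_B = E_B, E_W = E_W,
                    Psi = Psi, zeta = zeta, stringsAsFactors = FALSE)
  psi_df <- as.data.frame(t(psi_m))
  colnames(psi_df) <- paste0("psi_", p$block_labels)
  out <- cbind(out, psi_df)
  out$degenerate <- flag
  rownames(out) <- NULL
  attr(out, "block_labels") <- p$block_labels
  attr(out, "partition") <- p$name
  out
}
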
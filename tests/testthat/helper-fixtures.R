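# Build an ExpressionMatrix from a dense cells x genes matrix and a
# block-label vector in one call.
make_em <- function(mat, block = NULL, extra_meta = NULL) {
  n <- nrow(mat)
  cells <- sprintf("c%03d", seq_len(n))
  genes <- if (is.null(colnames(mat))) {
    sprintf("g%03d", seq_len(ncol(mat)))
  } else colnames(mat)
  meta <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  if (!is.null(block)) meta$block <- block
  if (!is.null(extra_meta)) meta <- cbind(meta, extra_meta)
  expression_matrix(mat, cells, genes, meta)
}

# Random sparse nonnegative gene vector: about `frac` of cells expressing,
# positive integer counts.
random_sparse_gene <- function(n, frac = 0.4) {
  x <- numeric(n)
  nz <- sample.int(n, max(2L, rbinom(1L, n, frac)))
  x[nz] <- rpois(length(nz), 4) + 1
  x
}

# Random partition of n cells into r nonempty blocks.
random_partition <- function(n, r) {
  repeat {
    a <- sample.int(r, n, replace = TRUE)
    if (length(unique(a)) == r) break
  }
  partition(a, paste0("b", seq_len(r)))
}

# Small scored table with q-values for the selection tests.
toy_scores <- function() {
  df <- data.frame(
    gene = c("mk1", "mk2", "insig", "hk1", "uniform", "weak"),
    Psi_mean = c(0.90, 0.80, 0.85, 0.82, 0.88, 0.40),
    zeta_mean = c(0.95, 0.80, 0.90, 0.02, 0.01, 0.60),
    psi_A = c(0.90, 0.85, 0.92, 0.50, 0.50, 0.70),
    psi_B = c(0.10, 0.15, 0.08, 0.50, 0.50, 0.30),
    q_Psi = c(0.001, 0.010, 0.200, 0.001, 0.300, 0.001),
    q_zeta = c(0.001, 0.010, 0.001, 0.900, 0.900, 0.010),
    q_psi_A = c(0.001, 0.010, 0.001, 0.500, 0.500, 0.010),
    q_psi_B = c(0.900, 0.900, 0.900, 0.500, 0.500, 0.900),
    stringsAsFactors = FALSE)
  attr(df, "block_labels") <- c("A", "B")
  df
}
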
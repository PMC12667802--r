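test_that("worked decompositions match hand values and the brute-force oracle", {
  cases <- list(
    list(x = c(2, 2, 4), blocks = list(1:2, 3),
         E_T = 1.5 * log(2), E_B = log(2), E_W = 0.5 * log(2),
         Psi = 1 / 3, psi = c(1, 0), zeta = 1),
    list(x = c(1, 1, 1, 1), blocks = list(1:2, 3:4),
         E_T = log(4), E_B = log(2), E_W = log(2),
         Psi = 0.5, psi = c(0.5, 0.5), zeta = 0),
    list(x = c(8, 2, 1, 1), blocks = list(1:2, 3:4),
         E_T = 0.9830784, E_B = 0.4505612, E_W = 0.5325265,
         Psi = 0.5416877, psi = c(0.7830633, 0.2169367), zeta = 0.2454656))
  for (cs in cases) {
    p <- blocks_to_partition(cs$blocks, length(cs$x))
    d <- decompose_entropy(cs$x, p)
    o <- oracle_scores(cs$x, cs$blocks)
    # frozen hand values (loose: printed to 7 digits)
    expect_equal(d$E_B, cs$E_B, tolerance = 1e-5)
    expect_equal(d$E_W, cs$E_W, tolerance = 1e-5)
    # oracle agreement at full precision
    expect_equal(d$E_T, o$E_T, tolerance = 1e-12)
    expect_equal(d$E_B, o$E_B, tolerance = 1e-12)
    expect_equal(d$E_B, o$E_B_direct, tolerance = 1e-10)
    expect_equal(d$E_W, o$E_W, tolerance = 1e-12)
    s <- specificity_scores(d)
    expect_equal(s$Psi, cs$Psi, tolerance = 1e-5)
    expect_equal(unname(s$psi_blocks), cs$psi, tolerance = 1e-5)
    expect_equal(s$zeta, cs$zeta, tolerance = 1e-5)
    expect_equal(s$Psi, o$Psi, tolerance = 1e-12)
    expect_equal(unname(s$psi_blocks), o$psi, tolerance = 1e-12)
    expect_equal(s$zeta, o$zeta, tolerance = 1e-12)
  }
})

test_that("all small integer vectors match the oracle to 1e-12", {
  # every 3-cell vector with entries 0..5 (sum > 0, both blocks expressed
  # or not - degenerate handling covered separately), blocks {1,2} | {3}
  blocks <- list(1:2, 3)
  p <- blocks_to_partition(blocks, 3)
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) {
    x <- c(a, b, cc)
    if (sum(x) == 0) next
    d <- decompose_entropy(x, p)
    o <- oracle_scores(x, blocks)
    expect_equal(d$E_T, o$E_T, tolerance = 1e-12)
    expect_equal(d$E_W, o$E_W, tolerance = 1e-12)
    if (o$E_T > 0 && o$E_W > 0) {
      s <- specificity_scores(d)
      expect_equal(s$Psi, o$Psi, tolerance = 1e-12)
      expect_equal(unname(s$psi_blocks), o$psi, tolerance = 1e-12)
      expect_equal(s$zeta, o$zeta, tolerance = 1e-12)
    }
  }
})

test_that("entropy conservation and psi normalization hold on random inputs", {
  set.seed(42)
  for (i in 1:100) {
    r <- sample(2:8, 1)
    n <- sample((2 * r):80, 1)
    p <- random_partition(n, r)
    x <- random_sparse_gene(n)
    d <- decompose_entropy(x, p)
    expect_lte(abs(d$E_T - (d$E_B + d$E_W)) / max(d$E_T, 1e-300), 1e-10)
    expect_equal(sum(d$p_C), 1, tolerance = 1e-12)
    expect_true(all(d$E_C >= 0))
    expect_lte(d$E_B, log(r) + 1e-10)
    s <- specificity_scores(d)
    if (s$degenerate_flag == "none") {
      expect_equal(sum(s$psi_blocks), 1, tolerance = 1e-10)
      expect_true(all(s$psi_blocks >= 0 & s$psi_blocks <= 1))
      expect_gte(s$Psi, 0); expect_lte(s$Psi, 1)
      expect_gte(s$zeta, 0); expect_lte(s$zeta, 1)
    }
  }
})

test_that("scale and log-base invariance of the ratio metrics", {
  set.seed(7)
  p <- random_partition(30, 4)
  x <- random_sparse_gene(30)
  s1 <- specificity_scores(decompose_entropy(x, p))
  s2 <- specificity_scores(decompose_entropy(x * 17.3, p))
  expect_equal(s1$Psi, s2$Psi, tolerance = 1e-12)
  expect_equal(s1$psi_blocks, s2$psi_blocks, tolerance = 1e-12)
  expect_equal(s1$zeta, s2$zeta, tolerance = 1e-12)
  # the oracle in base 2 must reproduce the package's (base-e) ratios
  blocks <- split(seq_len(30), p$assignment)
  o2 <- oracle_scores(x, blocks, base = 2)
  expect_equal(s1$Psi, o2$Psi, tolerance = 1e-12)
  expect_equal(unname(s1$psi_blocks), o2$psi, tolerance = 1e-12)
  expect_equal(s1$zeta, o2$zeta, tolerance = 1e-12)
})

test_that("block label order is irrelevant to Psi and zeta and permutes psi", {
  set.seed(8)
  n <- 40
  a <- sample.int(4, n, replace = TRUE)
  a[1:4] <- 1:4
  x <- random_sparse_gene(n)
  p1 <- partition(a, paste0("b", 1:4))
  perm <- c(3L, 1L, 4L, 2L)
  # same cell groups, blocks listed in a different order
  p2 <- partition(match(a, perm), paste0("b", perm))
  s1 <- specificity_scores(decompose_entropy(x, p1))
  s2 <- specificity_scores(decompose_entropy(x, p2))
  expect_identical(s1$Psi, s2$Psi)
  expect_identical(s1$zeta, s2$zeta)
  expect_equal(s2$psi_blocks[names(s1$psi_blocks)], s1$psi_blocks,
               tolerance = 1e-15)
})

test_that("between entropy is additive under hierarchical refinement", {
  set.seed(9)
  for (i in 1:30) {
    n <- 60
    coarse_a <- sample.int(3, n, replace = TRUE)
    coarse_a[1:3] <- 1:3
    # refine each coarse block into 2 sub-blocks
    sub <- sample.int(2, n, replace = TRUE)
    fine_a <- (coarse_a - 1L) * 2L + sub
    keep <- sort(unique(fine_a))
    fine_a <- match(fine_a, keep)
    x <- random_sparse_gene(n)
    coarse <- partition(coarse_a, paste0("C", 1:3))
    fine <- partition(fine_a, paste0("F", seq_along(keep)))
    expect_true(is_refinement(fine, coarse))
    d_f <- decompose_entropy(x, fine)
    d_c <- decompose_entropy(x, coarse)
    within_EB <- 0
    for (b in 1:3) {
      idx <- which(coarse_a == b)
      fa <- fine_a[idx]
      if (length(unique(fa)) < 2 || sum(x[idx]) == 0) next
      pr <- partition(match(fa, sort(unique(fa))),
                      paste0("s", seq_along(unique(fa))))
      within_EB <- within_EB + d_c$p_C[b] * decompose_entropy(x[idx], pr)$E_B
    }
    expect_equal(d_f$E_B, d_c$E_B + within_EB, tolerance = 1e-10)
  }
})

test_that("degenerate genes are flagged and handled as documented", {
  p <- blocks_to_partition(list(1:2, 3:4), 4)
  # a single expressing cell: E_T = 0
  s <- specificity_scores(decompose_entropy(c(0, 5, 0, 0), p))
  expect_equal(s$degenerate_flag, "zero_total")
  expect_true(is.na(s$Psi) && is.na(s$zeta))
  # one expressing cell per block: E_T > 0, E_W = 0
  s2 <- specificity_scores(decompose_entropy(c(3, 0, 0, 1), p))
  expect_equal(s2$degenerate_flag, "zero_within")
  expect_equal(s2$Psi, 0)
  expect_equal(unname(s2$psi_blocks), c(0.75, 0.25))
  expect_equal(s2$zeta, .zeta <- 1 - (-0.75 * log(0.75) - 0.25 * log(0.25)) / log(2))
  # zero everywhere is an error at the single-gene level
  expect_error(decompose_entropy(c(0, 0, 0, 0), p), "zero total")
})

test_that("block-exclusive expression gives Psi = 1, zeta = 1, indicator psi", {
  p <- blocks_to_partition(list(1:3, 4:6), 6)
  s <- specificity_scores(decompose_entropy(c(2, 3, 4, 0, 0, 0), p))
  expect_equal(s$Psi, 1, tolerance = 1e-15)
  expect_equal(unname(s$psi_blocks), c(1, 0), tolerance = 1e-15)
  expect_equal(s$zeta, 1, tolerance = 1e-15)
})

test_that("score_matrix agrees with the per-gene route and closed forms", {
  set.seed(10)
  n <- 24; r <- 3; G <- 15
  mat <- matrix(0, n, G)
  for (j in seq_len(G)) mat[, j] <- random_sparse_gene(n)
  mat[, 1] <- 1                              # uniform gene
  mat[, 2] <- c(rep(2, 8), rep(0, 16))        # block-exclusive gene
  a <- rep(1:3, each = 8)
  m <- make_em(mat, block = paste0("b", a))
  p <- partition_from_metadata(m, "block")
  tab <- score_matrix(m, p)
  for (j in seq_len(G)) {
    s <- specificity_scores(decompose_entropy(mat[, j], p))
    if (s$degenerate_flag == "none") {
      expect_equal(tab$Psi[j], s$Psi, tolerance = 1e-12)
      expect_equal(tab$zeta[j], s$zeta, tolerance = 1e-12)
      expect_equal(unname(unlist(tab[j, paste0("psi_", p$block_labels)])),
                   unname(s$psi_blocks), tolerance = 1e-12)
    }
  }
  # uniform gene over r equal blocks of m cells: Psi = log m / log(rm)
  expect_equal(tab$Psi[1], log(8) / log(24), tolerance = 1e-12)
  expect_equal(tab$zeta[1], 0, tolerance = 1e-12)
  expect_equal(tab$Psi[2], 1, tolerance = 1e-12)
  expect_equal(tab$zeta[2], 1, tolerance = 1e-12)
})

test_that("score_matrix has no cross-gene coupling and flags zero genes", {
  set.seed(12)
  mat <- matrix(rpois(60, 2), 12, 5)
  mat[, 3] <- 0
  m <- make_em(mat, block = rep(c("u", "v"), 6))
  p <- partition_from_metadata(m, "block")
  tab <- score_matrix(m, p)
  expect_equal(tab$degenerate[3], "zero_total")
  expect_true(is.na(tab$Psi[3]))
  # permuting gene columns permutes rows identically
  ord <- c(4, 2, 5, 1, 3)
  m2 <- expression_matrix(m$values[, ord], m$cell_ids, m$gene_ids[ord],
                          m$cell_metadata)
  tab2 <- score_matrix(m2, p)
  expect_equal(tab2$Psi, tab$Psi[ord])
  expect_equal(tab2$gene, tab$gene[ord])
})
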
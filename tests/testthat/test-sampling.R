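mice_meta <- function(per_pair = 3) {
  grid <- expand.grid(strain = c("A", "B"), sex = c("F", "M"),
                      rep = seq_len(per_pair), stringsAsFactors = FALSE)
  grid$mouse <- sprintf("%s_%s_%d", grid$strain, grid$sex, grid$rep)
  # two cells per mouse
  idx <- rep(seq_len(nrow(grid)), each = 2)
  data.frame(cell_id = sprintf("c%03d", seq_along(idx)),
             strain = grid$strain[idx], sex = grid$sex[idx],
             mouse = grid$mouse[idx], stringsAsFactors = FALSE)
}

test_that("each balanced draw holds one sample per category-condition pair", {
  meta <- mice_meta(3)
  des <- sampling_design("strain", "sex", "mouse", n_draws = 3, seed = 5)
  draws <- balanced_draws(meta, des)
  expect_length(draws, 3)
  for (d in draws) {
    expect_length(d, 4)  # 2 strains x 2 sexes
    picked <- unique(meta[meta$mouse %in% d, c("strain", "sex")])
    expect_equal(nrow(picked), 4L)
  }
  # least-used rule: with 3 mice per pair and 3 draws, every mouse is used
  # exactly once
  usage <- table(unlist(draws))
  expect_true(all(usage == 1))
  expect_equal(length(usage), 12L)
})

test_that("draws are reproducible for a fixed seed and change with it", {
  meta <- mice_meta(4)
  d1 <- balanced_draws(meta, sampling_design("strain", "sex", "mouse",
                                             n_draws = 10, seed = 3))
  d2 <- balanced_draws(meta, sampling_design("strain", "sex", "mouse",
                                             n_draws = 10, seed = 3))
  d3 <- balanced_draws(meta, sampling_design("strain", "sex", "mouse",
                                             n_draws = 10, seed = 4))
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
})

test_that("a pair with a single sample is forced into every draw", {
  meta <- mice_meta(2)
  meta <- meta[!(meta$mouse %in% c("A_F_2")), ]
  des <- sampling_design("strain", "sex", "mouse", n_draws = 6, seed = 1)
  draws <- balanced_draws(meta, des)
  expect_true(all(vapply(draws, function(d) "A_F_1" %in% d, logical(1))))
})

test_that("an empty category-condition pair is a balance error naming it", {
  meta <- mice_meta(2)
  meta <- meta[!(meta$strain == "B" & meta$sex == "M"), ]
  des <- sampling_design("strain", "sex", "mouse", n_draws = 2, seed = 1)
  expect_error(balanced_draws(meta, des), "B:M")
})

test_that("scores_over_draws restricts cells per draw and flags lost genes", {
  set.seed(21)
  meta <- mice_meta(2)
  n <- nrow(meta)
  mat <- matrix(rpois(n * 4, 3) + 1, n, 4)
  # gene 4 expressed only in mouse A_F_1's cells
  mat[, 4] <- 0
  mat[meta$mouse == "A_F_1", 4] <- 5
  m <- expression_matrix(mat, meta$cell_id, paste0("g", 1:4), meta)
  p <- partition_from_metadata(m, "strain")
  des <- sampling_design("strain", "sex", "mouse", n_draws = 4, seed = 2)
  draws <- balanced_draws(meta, des)
  per <- scores_over_draws(m, p, draws, des)
  expect_length(per, 4)
  has_af1 <- vapply(draws, function(d) "A_F_1" %in% d, logical(1))
  for (k in seq_along(per)) {
    expect_equal(per[[k]]$degenerate[4],
                 if (has_af1[k]) "none" else "zero_total")
  }
})

test_that("forced identical draws give identical tables and zero SDs", {
  meta <- mice_meta(1)  # single mouse per pair: every draw identical
  set.seed(3)
  mat <- matrix(rpois(nrow(meta) * 3, 4) + 1, nrow(meta), 3)
  m <- expression_matrix(mat, meta$cell_id, paste0("g", 1:3), meta)
  p <- partition_from_metadata(m, "strain")
  des <- sampling_design("strain", "sex", "mouse", n_draws = 5, seed = 9)
  per <- scores_over_draws(m, p, balanced_draws(meta, des), des)
  expect_true(all(vapply(per[-1], identical, logical(1), per[[1]])))
  ag <- aggregate_draws(per)
  expect_true(all(ag$Psi_sd == 0))
  expect_true(all(ag$zeta_sd == 0))
  expect_true(all(ag[, grepl("_gsd$", colnames(ag))] == 1))
  expect_equal(ag$Psi_mean, per[[1]]$Psi)
})

test_that("aitchison_mean reproduces identity and hand-computed cases", {
  id <- aitchison_mean(rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(id$mean, c(0.5, 0.5))
  expect_equal(id$gsd, c(1, 1))
  # two draws [0.8, 0.2] and [0.2, 0.8]: geometric means (0.4, 0.4)
  hand <- aitchison_mean(rbind(c(0.8, 0.2), c(0.2, 0.8)))
  expect_equal(hand$mean, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(hand$gsd[1], hand$gsd[2], tolerance = 1e-12)
  one <- aitchison_mean(matrix(c(0.3, 0.7), 1))
  expect_equal(one$mean, c(0.3, 0.7))
  expect_equal(one$gsd, c(1, 1))
})

test_that("aitchison mean is perturbation-equivariant", {
  set.seed(13)
  comps <- t(apply(matrix(rgamma(60, 2), 15, 4), 1, function(v) v / sum(v)))
  pert <- c(2, 0.5, 1.3, 0.2)
  pert_comps <- t(apply(comps, 1, function(v) v * pert / sum(v * pert)))
  m1 <- aitchison_mean(comps)$mean
  m2 <- aitchison_mean(pert_comps)$mean
  expect_equal(m2, m1 * pert / sum(m1 * pert), tolerance = 1e-10)
})

test_that("zero components are handled by multiplicative replacement", {
  comps <- rbind(c(1, 0), c(0.5, 0.5))
  ag <- aitchison_mean(comps)
  expect_equal(ag$delta, 0.25)  # half the smallest nonzero (0.5)
  expect_equal(sum(ag$mean), 1, tolerance = 1e-12)
  expect_true(all(ag$mean > 0))
  expect_true(all(ag$gsd >= 1))
})

test_that("aggregate_draws summary statistics are textbook", {
  # two draws differing only in Psi/zeta for one gene
  t1 <- data.frame(gene = "g1", Psi = 0.2, zeta = 0.3, psi_a = 0.8,
                   psi_b = 0.2, degenerate = "none",
                   stringsAsFactors = FALSE)
  t2 <- t1; t2$Psi <- 0.4; t2$zeta <- 0.5
  t2$psi_a <- 0.2; t2$psi_b <- 0.8
  per <- list(t1, t2)
  attr(per, "block_labels") <- c("a", "b")
  ag <- aggregate_draws(per)
  expect_equal(ag$Psi_mean, 0.3)
  expect_equal(ag$Psi_sd, sd(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(ag$Psi_sd, 0.1414214, tolerance = 1e-6)
  expect_equal(c(ag$psi_a, ag$psi_b), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(ag$n_draws_used, 2L, ignore_attr = TRUE)
})
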
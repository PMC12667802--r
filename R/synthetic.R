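#' Design for a synthetic factorial expression dataset
#'
#' Emulates the structure of a factorial single-cell atlas: crossed
#' categorical factors (e.g. strain x sex x tissue), several biological
#' replicates (samples) per factor combination, and a fixed number of cells
#' per sample. Three gene classes with known ground truth are planted:
#' \emph{markers}, enriched by a fold factor inside one target block of the
#' marker factor; \emph{housekeeping} genes expressed at one common mean
#' everywhere; and \emph{noise} genes with sparse low expression and no
#' block structure.
#'
#' Counts follow a negative binomial with log-scale factor effects and a
#' lognormal sample-level random effect, the simplest model reproducing the
#' overdispersion and replicate-to-replicate variability of real single-cell
#' counts. It is a test scaffold with known truth, not a fit to any real
#' dataset: it has no dropout model, no library-size variation within a
#' sample, and no correlated gene programs.
#'
#' @param factors named list of character level vectors, e.g.
#'   \code{list(strain = c("A","B"), sex = c("F","M"))}.
#' @param samples_per_combo replicates per factor combination (default 3).
#' @param cells_per_sample cells per replicate (default 50).
#' @param marker_factor name of the factor whose levels receive planted
#'   markers (default: the first factor).
#' @param n_markers_per_block planted markers per level of the marker
#'   factor (default 5).
#' @param n_housekeeping planted invariant genes (default 10).
#' @param n_noise unstructured sparse genes (default 20).
#' @param baseline_mean negative-binomial mean of an unenriched expressed
#'   gene (default 5).
#' @param marker_fold fold-enrichment of a marker inside its target block
#'   (> 1; default 8). Use \code{Inf} for block-exclusive expression
#'   (outside baseline forced to 0).
#' @param marker_baseline small mean of a marker outside its target block
#'   (default \code{baseline_mean / 20}).
#' @param noise_mean mean of noise genes (default 0.3, giving sparse
#'   expression).
#' @param dispersion negative-binomial dispersion (1/size; default 0.5).
#' @param sample_sdlog lognormal SD of the per-sample random effect
#'   (default 0.2).
#' @param seed integer seed.
#' @return list of class \code{SimulationDesign}.
#' @export
simulation_design <- function(factors, samples_per_combo = 3,
                              cells_per_sample = 50,
                              marker_factor = names(factors)[1L],
                              n_markers_per_block = 5, n_housekeeping = 10,
                              n_noise = 20, baseline_mean = 5,
                              marker_fold = 8,
                              marker_baseline = baseline_mean / 20,
                              noise_mean = 0.3, dispersion = 0.5,
                              sample_sdlog = 0.2, seed = 1L) {
  stopifnot(is.list(factors), length(factors) >= 1L, !is.null(names(factors)))
  if (any(lengths(factors) < 1L)) stop("each factor needs >= 1 level")
  if (length(factors[[marker_factor]]) < 2L) {
    stop("marker factor must have at least 2 levels", call. = FALSE)
  }
  if (marker_fold <= 1) stop("marker_fold must exceed 1", call. = FALSE)
  structure(list(factors = factors, samples_per_combo = samples_per_combo,
                 cells_per_sample = cells_per_sample,
                 marker_factor = marker_factor,
                 n_markers_per_block = n_markers_per_block,
                 n_housekeeping = n_housekeeping, n_noise = n_noise,
                 baseline_mean = baseline_mean, marker_fold = marker_fold,
                 marker_baseline = marker_baseline,
                 noise_mean = noise_mean, dispersion = dispersion,
                 sample_sdlog = sample_sdlog, seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' Simulate an expression matrix with known ground truth
#'
#' @param design a \code{\link{simulation_design}}.
#' @return list with \code{matrix} (an \code{ExpressionMatrix} whose
#'   metadata has one column per factor plus \code{sample_id}) and
#'   \code{truth} (data.frame: \code{gene}, \code{class} in
#'   marker/housekeeping/noise, \code{target_block} for markers).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  combos <- expand.grid(design$factors, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  n_samp <- nrow(combos) * design$samples_per_combo
  samp_meta <- combos[rep(seq_len(nrow(combos)),
                          each = design$samples_per_combo), , drop = FALSE]
  samp_meta$sample_id <- sprintf("s%03d", seq_len(n_samp))
  cells <- samp_meta[rep(seq_len(n_samp), each = design$cells_per_sample), ,
                     drop = FALSE]
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("c%05d", seq_len(n_cells))
  rownames(cells) <- NULL

  mf_levels <- design$factors[[design$marker_factor]]
  truth <- data.frame(
    gene = character(0), class = character(0), target_block = character(0),
    stringsAsFactors = FALSE)
  gene_means <- list()  # per gene: length-n_cells mean vector (pre sample effect)
  cell_block <- cells[[design$marker_factor]]
  g <- 0L
  add_gene <- function(name, class, target, mu) {
    g <<- g + 1L
    truth[g, ] <<- list(name, class, target)
    gene_means[[g]] <<- mu
  }
  for (lv in mf_levels) {
    for (k in seq_len(design$n_markers_per_block)) {
      inb <- cell_block == lv
      mu <- numeric(n_cells)
      if (is.infinite(design$marker_fold)) {
        mu[inb] <- design$baseline_mean
        mu[!inb] <- 0
      } else {
        mu[inb] <- design$baseline_mean * design$marker_fold
        mu[!inb] <- design$marker_baseline
      }
      add_gene(sprintf("marker_%s_%02d", lv, k), "marker", lv, mu)
    }
  }
  for (k in seq_len(design$n_housekeeping)) {
    add_gene(sprintf("hk_%02d", k), "housekeeping", NA_character_,
             rep(design$baseline_mean, n_cells))
  }
  for (k in seq_len(design$n_noise)) {
    add_gene(sprintf("noise_%02d", k), "noise", NA_character_,
             rep(design$noise_mean, n_cells))
  }
  G <- g
  # per-sample lognormal random effect, shared across genes
  samp_eff <- stats::rlnorm(n_samp, meanlog = 0, sdlog = design$sample_sdlog)
  names(samp_eff) <- samp_meta$sample_id
  cell_eff <- samp_eff[cells$sample_id]
  size <- 1 / design$dispersion
  counts <- matrix(0L, n_cells, G)
  for (j in seq_len(G)) {
    mu <- gene_means[[j]] * cell_eff
    pos <- mu > 0
    counts[pos, j] <- stats::rnbinom(sum(pos), size = size, mu = mu[pos])
  }
  meta <- cells[, c("cell_id", names(design$factors), "sample_id")]
  m <- expression_matrix(Matrix::Matrix(counts, sparse = TRUE),
                         cells$cell_id, truth$gene, meta)
  list(matrix = m, truth = truth)
}

#' Simulate block-exchangeable null data
#'
#' Expression independent of block labels by construction: every gene's
#' counts are i.i.d. negative binomial across cells, and cells are assigned
#' to r equal (or near-equal) blocks. Used to calibrate the permutation
#' test — observed specificity should look like its own permutation null.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes.
#' @param r number of blocks (>= 2).
#' @param seed integer seed.
#' @param mean,dispersion negative-binomial parameters (defaults 5, 0.5).
#' @return list with \code{matrix} (ExpressionMatrix with a \code{block}
#'   metadata column) and \code{partition}.
#' @export
simulate_null <- function(n_cells, n_genes, r, seed = 1L, mean = 5,
                          dispersion = 0.5) {
  stopifnot(r >= 2, n_cells >= 2 * r)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_cells * n_genes, size = 1 / dispersion,
                                  mu = mean), n_cells, n_genes)
  cell_ids <- sprintf("c%05d", seq_len(n_cells))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  block <- sprintf("b%d", rep_len(seq_len(r), n_cells))
  meta <- data.frame(cell_id = cell_ids, block = block,
                     stringsAsFactors = FALSE)
  m <- expression_matrix(Matrix::Matrix(counts, sparse = TRUE), cell_ids,
                         gene_ids, meta)
  list(matrix = m, partition = partition_from_metadata(m, "block"))
}

#' Write a simulated fixture bundle to disk
#'
#' Writes the matrix as Matrix Market + TSV sidecars (via
#' \code{\link{write_matrix}}) plus \code{truth.json} recording every
#' gene's class and target block.
#'
#' @param sim result of \code{\link{simulate_expression}}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_fixture <- function(sim, dir) {
  write_matrix(sim$matrix, dir)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}
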
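#' End-to-end specificity scoring workflow
#'
#' Runs the standardized workflow: gene filtering, partition construction
#' (including interaction terms), balanced replicate draws, per-draw
#' scoring, aggregation, permutation p-values and one global BH correction
#' pooled across every metric and every partition. All randomness flows
#' from \code{seed}, so a rerun with an identical configuration reproduces
#' the output byte for byte; results are also independent of
#' \code{chunk_size}, which only controls how many genes are processed at a
#' time.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param partitions list of character vectors of metadata column names;
#'   each element defines one partition (length > 1 means an interaction
#'   term such as \code{c("sex", "strain", "tissue")}). A single character
#'   vector is treated as one partition.
#' @param design optional \code{\link{sampling_design}} enabling balanced
#'   replicate draws; its seed is overridden by \code{seed}. When NULL the
#'   scores come from the full matrix and SDs are 0.
#' @param n_permutations permutations for the significance tests (default
#'   100); 0 disables inference.
#' @param seed integer seed governing draws and permutations (mandatory
#'   when any stochastic step runs).
#' @param min_cells gene filter threshold (default 100; see
#'   \code{\link{filter_genes}}).
#' @param chunk_size optional number of genes per processing chunk.
#' @param out_dir optional directory; when given, one
#'   \code{scores_<partition>.tsv} per partition plus
#'   \code{provenance.json} are written.
#' @param verbose log per-stage gene counts (default TRUE).
#' @return list with \code{scores} (named list of per-partition score
#'   data.frames, q-values pooled globally) and \code{provenance} (the
#'   machine-readable run record).
#' @export
score_pipeline <- function(m, partitions, design = NULL,
                           n_permutations = 100, seed = NULL,
                           min_cells = 100, chunk_size = NULL,
                           out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.character(partitions)) partitions <- list(partitions)
  stochastic <- !is.null(design) || n_permutations > 0
  if (stochastic && is.null(seed)) {
    stop("seed is mandatory when sampling or permutation testing runs",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- 0L
  seed <- as.integer(seed)
  say <- function(...) if (verbose) message(...)

  n_before <- length(m$gene_ids)
  m <- filter_genes(m, min_cells = min_cells, verbose = FALSE)
  say("filter_genes: ", length(m$gene_ids), "/", n_before, " genes retained")

  chunks <- if (is.null(chunk_size)) list(seq_along(m$gene_ids)) else {
    split(seq_along(m$gene_ids),
          ceiling(seq_along(m$gene_ids) / chunk_size))
  }
  part_names <- vapply(partitions, paste, character(1L), collapse = ":")
  tables <- vector("list", length(partitions))
  names(tables) <- part_names
  for (i in seq_along(partitions)) {
    p <- partition_from_metadata(m, partitions[[i]])
    draws <- NULL
    if (!is.null(design)) {
      design$seed <- seed
      draws <- balanced_draws(m$cell_metadata, design)
    }
    # chunking only subsets genes; the seeded RNG streams draw cell
    # permutations and sample picks, so chunked results are identical
    per_chunk <- lapply(chunks, function(idx) {
      mc <- expression_matrix(m$values[, idx, drop = FALSE], m$cell_ids,
                              m$gene_ids[idx], m$cell_metadata)
      obs <- if (!is.null(draws)) {
        aggregate_draws(suppressWarnings(
          scores_over_draws(mc, p, draws, design)))
      } else {
        score_matrix(mc, p)
      }
      if (n_permutations > 0) {
        pv <- permutation_pvalues(mc, p, obs,
                                  n_permutations = n_permutations,
                                  seed = seed + i, draws = draws,
                                  design = design)
        obs <- cbind(obs, pv[match(obs$gene, pv$gene),
                             setdiff(colnames(pv), "gene"), drop = FALSE])
      }
      obs
    })
    tab <- do.call(rbind, per_chunk)
    rownames(tab) <- NULL
    attr(tab, "block_labels") <- p$block_labels
    attr(tab, "partition") <- p$name
    tables[[i]] <- tab
    say("partition ", p$name, ": ", nrow(tab), " genes scored over ",
        n_blocks(p), " blocks")
  }
  if (n_permutations > 0) {
    labs <- lapply(tables, attr, "block_labels")
    tables <- add_global_qvalues(tables)
    for (i in seq_along(tables)) {
      attr(tables[[i]], "block_labels") <- labs[[i]]
      attr(tables[[i]], "partition") <- part_names[i]
    }
  }
  provenance <- list(
    package = "entrospec",
    version = as.character(utils::packageVersion("entrospec")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    partitions = partitions,
    sampling = if (is.null(design)) NULL else {
      design[c("category_column", "condition_column", "sample_id_column",
               "n_draws")]
    },
    n_permutations = n_permutations,
    min_cells = min_cells,
    chunk_size = chunk_size,
    seed = seed,
    n_cells = length(m$cell_ids),
    n_genes = length(m$gene_ids))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(tables)) {
      write_scores(tables[[nm]],
                   file.path(out_dir, paste0(
                     "scores_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv")))
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  list(scores = tables, provenance = provenance)
}
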
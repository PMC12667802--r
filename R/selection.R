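#' Thresholds for gene selection
#'
#' Collects the metric thresholds used by the selection workflows. All
#' comparisons against thresholds are strict (a gene must exceed a minimum
#' or fall below a maximum); the significance gate \code{q < q_max} is
#' applied before any threshold. Defaults follow the convention of 0.5 in
#' the absence of prior biological knowledge.
#'
#' @param psi_block_min minimum psi_block for marker selection (default 0.5).
#' @param Psi_min minimum Psi (default 0.5).
#' @param zeta_min minimum zeta for partition-specific selection
#'   (default 0.5).
#' @param zeta_max maximum zeta for housekeeping selection (no default; must
#'   be set explicitly for that workflow).
#' @param q_max q-value cutoff (default 0.05).
#' @return A list of class \code{SelectionRule}.
#' @export
selection_rule <- function(psi_block_min = 0.5, Psi_min = 0.5,
                           zeta_min = 0.5, zeta_max = NULL, q_max = 0.05) {
  chk <- function(v, nm) {
    if (!is.null(v) && (v < 0 || v > 1)) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  chk(psi_block_min, "psi_block_min"); chk(Psi_min, "Psi_min")
  chk(zeta_min, "zeta_min"); chk(zeta_max, "zeta_max"); chk(q_max, "q_max")
  structure(list(psi_block_min = psi_block_min, Psi_min = Psi_min,
                 zeta_min = zeta_min, zeta_max = zeta_max, q_max = q_max),
            class = "SelectionRule")
}

.score_col <- function(scores, base) {
  cn <- paste0(base, "_mean")
  if (cn %in% colnames(scores)) scores[[cn]] else scores[[base]]
}

.require_block <- function(scores, block) {
  blocks <- attr(scores, "block_labels")
  if (is.null(blocks)) {
    blocks <- sub("^psi_", "",
                  grep("^psi_(?!.*_gsd$)", colnames(scores), value = TRUE,
                       perl = TRUE))
  }
  if (!block %in% blocks) {
    stop("unknown block \"", block, "\"; valid blocks: ",
         paste(blocks, collapse = ", "), call. = FALSE)
  }
}

.rank_order <- function(scores, keys, decreasing) {
  args <- lapply(seq_along(keys), function(i) {
    v <- keys[[i]]
    if (decreasing[i]) -xtfrm(v) else xtfrm(v)
  })
  do.call(order, c(args, list(xtfrm(scores$gene))))
}

#' Select marker genes for one block
#'
#' Markers are genes whose informative expression concentrates in the
#' chosen block: high psi_block for that block and high Psi, both
#' significant after permutation testing. A gene significant by psi_block
#' alone but not by Psi is excluded — both gates must pass. Results are
#' ranked by descending psi_block, then Psi, then gene id.
#'
#' @param scores aggregated score table with \code{q_*} columns.
#' @param block block label to select markers for.
#' @param rule a \code{\link{selection_rule}}.
#' @return The selected rows of \code{scores}, ranked; zero rows when no
#'   gene passes.
#' @export
select_markers <- function(scores, block, rule = selection_rule()) {
  .require_block(scores, block)
  psi <- scores[[paste0("psi_", block)]]
  Psi <- .score_col(scores, "Psi")
  q_psi <- scores[[paste0("q_psi_", block)]]
  q_Psi <- scores[["q_Psi"]]
  if (is.null(q_psi) || is.null(q_Psi)) {
    stop("scores lack q-value columns; run add_global_qvalues first",
         call. = FALSE)
  }
  keep <- !is.na(psi) & !is.na(Psi) & !is.na(q_psi) & !is.na(q_Psi) &
    q_psi < rule$q_max & q_Psi < rule$q_max &
    psi > rule$psi_block_min & Psi > rule$Psi_min
  sel <- scores[keep, , drop = FALSE]
  sel[.rank_order(sel, list(sel[[paste0("psi_", block)]],
                            .score_col(sel, "Psi")),
                  c(TRUE, TRUE)), , drop = FALSE]
}

#' Select genes specific to a partition
#'
#' Partition-specific genes have both high Psi (the partition explains
#' their expression information) and high zeta (that information is
#' concentrated in few blocks), each significant. Ranked by descending
#' zeta, then Psi, then gene id.
#'
#' @inheritParams select_markers
#' @export
select_partition_specific <- function(scores, rule = selection_rule()) {
  Psi <- .score_col(scores, "Psi")
  zeta <- .score_col(scores, "zeta")
  q_Psi <- scores[["q_Psi"]]
  q_zeta <- scores[["q_zeta"]]
  if (is.null(q_Psi) || is.null(q_zeta)) {
    stop("scores lack q-value columns; run add_global_qvalues first",
         call. = FALSE)
  }
  keep <- !is.na(Psi) & !is.na(zeta) & !is.na(q_Psi) & !is.na(q_zeta) &
    q_Psi < rule$q_max & q_zeta < rule$q_max &
    Psi > rule$Psi_min & zeta > rule$zeta_min
  sel <- scores[keep, , drop = FALSE]
  sel[.rank_order(sel, list(.score_col(sel, "zeta"), .score_col(sel, "Psi")),
                  c(TRUE, TRUE)), , drop = FALSE]
}

#' Select housekeeping-like genes
#'
#' Housekeeping genes carry information explained by the partition (high
#' Psi, significant) but spread it evenly across blocks (low zeta point
#' estimate). Ranked by ascending zeta, then descending Psi, then gene id.
#' \code{rule$zeta_max} must be set.
#'
#' @inheritParams select_markers
#' @export
select_housekeeping <- function(scores, rule) {
  if (is.null(rule$zeta_max)) {
    stop("selection rule is incomplete: zeta_max must be set for ",
         "housekeeping selection", call. = FALSE)
  }
  Psi <- .score_col(scores, "Psi")
  zeta <- .score_col(scores, "zeta")
  q_Psi <- scores[["q_Psi"]]
  if (is.null(q_Psi)) {
    stop("scores lack q-value columns; run add_global_qvalues first",
         call. = FALSE)
  }
  keep <- !is.na(Psi) & !is.na(zeta) & !is.na(q_Psi) &
    q_Psi < rule$q_max & Psi > rule$Psi_min & zeta < rule$zeta_max
  sel <- scores[keep, , drop = FALSE]
  sel[.rank_order(sel, list(.score_col(sel, "zeta"), .score_col(sel, "Psi")),
                  c(FALSE, TRUE)), , drop = FALSE]
}

#' Membership table for UpSet plots
#'
#' Builds the boolean gene-by-set membership matrix and the exclusive
#' intersection regions (every gene counted in exactly one region), the
#' inputs UpSet plotting tools consume.
#'
#' @param sets named list (>= 2 entries) of character gene vectors, e.g.
#'   per-partition selections.
#' @return list with \code{membership} (data.frame: gene + one logical
#'   column per set) and \code{regions} (data.frame: \code{region} label
#'   joining member sets with \code{"&"}, \code{degree}, \code{count},
#'   \code{genes} comma-joined).
#' @export
upset_membership <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  genes <- sort(unique(unlist(sets)))
  mem <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) mem <- matrix(mem, nrow = 1L,
                                         dimnames = list(NULL, names(sets)))
  membership <- data.frame(gene = genes, mem, check.names = FALSE,
                           stringsAsFactors = FALSE)
  key <- apply(mem, 1L, function(z) paste(names(sets)[z], collapse = "&"))
  tab <- table(key)
  region <- if (length(tab)) names(sort(tab, decreasing = TRUE)) else {
    character(0)
  }
  regions <- data.frame(
    region = region,
    degree = lengths(strsplit(region, "&", fixed = TRUE)),
    count = as.integer(tab[region]),
    genes = vapply(region, function(rg) {
      paste(genes[key == rg], collapse = ",")
    }, character(1L)),
    stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  list(membership = membership, regions = regions)
}

#' Gene-by-block feature matrix of Aitchison-mean psi_block values
#'
#' Extracts the aggregated psi_block composition as a dense gene x block
#' matrix with stable ordering — the feature matrix the clustering
#' workflows (e.g. Leiden on a nearest-neighbor graph) consume. Degenerate
#' genes (any missing component) are excluded and listed in the
#' \code{excluded} attribute.
#'
#' @param scores aggregated score table.
#' @param out_path optional TSV path to write the matrix to.
#' @return numeric matrix, rows = genes (named), columns = blocks in
#'   partition order; rows sum to 1.
#' @export
psi_feature_matrix <- function(scores, out_path = NULL) {
  blocks <- attr(scores, "block_labels")
  if (is.null(blocks)) {
    cand <- grep("^psi_", colnames(scores), value = TRUE)
    blocks <- sub("^psi_", "", cand[!grepl("_gsd$", cand)])
  }
  cols <- paste0("psi_", blocks)
  mat <- as.matrix(scores[, cols, drop = FALSE])
  rownames(mat) <- scores$gene
  colnames(mat) <- blocks
  ok <- stats::complete.cases(mat)
  excluded <- scores$gene[!ok]
  mat <- mat[ok, , drop = FALSE]
  if (!is.null(out_path)) {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (length(excluded)) {
      writeLines(excluded, paste0(out_path, ".excluded"))
    }
  }
  attr(mat, "excluded") <- excluded
  mat
}
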
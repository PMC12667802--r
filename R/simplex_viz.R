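#' Regular polygon layout for compositional projection
#'
#' A composition over r blocks lives on an (r-1)-simplex; projecting its
#' barycentric coordinates onto the vertices of a regular r-gon gives a 2D
#' picture in which proximity to a vertex means specificity to that block.
#' Vertices are equally spaced on the unit circle, the first at angle
#' pi/2 (top), proceeding counter-clockwise. Because the polygon can be
#' rotated and reflected without changing the picture, there are
#' (r-1)!/2 genuinely different vertex orderings; the ordering is
#' biological knowledge (e.g. genetic distance between strains) and is
#' supplied by the user, defaulting to the partition's block order.
#'
#' @param block_labels character vector of r >= 3 block labels, in the
#'   desired vertex order (vertex 1 = top, then counter-clockwise).
#' @return list of class \code{PolygonLayout}: \code{r},
#'   \code{vertex_order}, and \code{vertex_coords} (r x 2 matrix).
#' @export
polygon_layout <- function(block_labels) {
  block_labels <- as.character(block_labels)
  r <- length(block_labels)
  if (r < 3L) stop("polygon layout requires at least 3 blocks", call. = FALSE)
  if (anyDuplicated(block_labels)) {
    stop("vertex labels must be unique", call. = FALSE)
  }
  theta <- pi / 2 + 2 * pi * (seq_len(r) - 1L) / r
  coords <- cbind(x = cos(theta), y = sin(theta))
  rownames(coords) <- block_labels
  structure(list(r = r, vertex_order = block_labels,
                 vertex_coords = coords),
            class = "PolygonLayout")
}

#' Project a composition onto a polygon layout
#'
#' Barycentric projection: the point is the composition-weighted average of
#' the vertex coordinates, so it always lies in the polygon's convex hull.
#' A unit mass on one block lands exactly on that block's vertex; the
#' uniform composition lands on the centroid (0, 0). The projection is
#' affine in the composition.
#'
#' @param psi length-r nonnegative composition summing to 1 (within 1e-8).
#'   If named, names are matched to the layout's vertex labels; otherwise
#'   components are taken in vertex order.
#' @param layout a \code{\link{polygon_layout}}.
#' @return numeric c(x, y).
#' @export
project_composition <- function(psi, layout) {
  stopifnot(inherits(layout, "PolygonLayout"))
  if (length(psi) != layout$r) {
    stop("composition length ", length(psi), " does not match layout with ",
         layout$r, " vertices", call. = FALSE)
  }
  if (any(psi < 0) || abs(sum(psi) - 1) > 1e-8) {
    stop("composition must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!is.null(names(psi))) {
    if (!setequal(names(psi), layout$vertex_order)) {
      stop("composition names do not match layout vertex labels",
           call. = FALSE)
    }
    psi <- psi[layout$vertex_order]
  }
  as.numeric(colSums(layout$vertex_coords * as.numeric(psi)))
}

#' Number of distinct polygon projections of a simplex
#'
#' An (r-1)-simplex projected onto a regular r-gon admits one 2D picture
#' per vertex ordering, but orderings related by rotating or reflecting
#' the polygon give the same picture, leaving r!/(2r) = (r-1)!/2 distinct
#' projections.
#'
#' @param r number of polygon vertices (>= 3).
#' @return integer count of distinct projections.
#' @export
count_unique_layouts <- function(r) {
  if (r < 3) stop("r must be at least 3", call. = FALSE)
  factorial(r - 1) / 2
}

#' Project per-draw compositions and their Aitchison mean
#'
#' @param comps matrix of compositions (one per row, e.g. per balanced
#'   draw), columns named by block.
#' @param layout a \code{\link{polygon_layout}}.
#' @return data.frame with columns \code{x}, \code{y} and \code{kind}
#'   ("draw" rows followed by one "mean" row, the projected Aitchison
#'   mean).
#' @export
project_draws <- function(comps, layout) {
  comps <- as.matrix(comps)
  pts <- t(apply(comps, 1L, function(row) {
    v <- row
    names(v) <- colnames(comps)
    project_composition(v / sum(v), layout)
  }))
  center <- aitchison_mean(comps)$mean
  names(center) <- colnames(comps)
  cp <- project_composition(center, layout)
  data.frame(x = c(pts[, 1L], cp[1L]), y = c(pts[, 2L], cp[2L]),
             kind = c(rep("draw", nrow(comps)), "mean"),
             stringsAsFactors = FALSE)
}

#' Polygon cloud plot of per-draw specificity compositions
#'
#' Draws the polygon outline with vertex labels, each per-draw composition
#' as a grey point, and the Aitchison mean as a star — the standard way to
#' show how a gene's block specificity varies across balanced replicate
#' draws.
#'
#' @param points data.frame from \code{\link{project_draws}} (or any frame
#'   with \code{x}, \code{y}, \code{kind} columns where \code{kind} is
#'   "draw" or "mean").
#' @param layout a \code{\link{polygon_layout}}.
#' @param title optional plot title (e.g. the gene name).
#' @return A ggplot object; save with \code{ggplot2::ggsave()} as SVG/PDF.
#' @export
draw_cloud <- function(points, layout, title = NULL) {
  stopifnot(inherits(layout, "PolygonLayout"), nrow(points) >= 1L)
  vc <- as.data.frame(layout$vertex_coords)
  colnames(vc) <- c("x", "y")
  vc$label <- layout$vertex_order
  ring <- vc[c(seq_len(layout$r), 1L), ]
  gg <- ggplot2::ggplot() +
    ggplot2::geom_path(data = ring, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "grey40") +
    ggplot2::geom_text(data = vc,
                       ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                                    label = .data$label), size = 3) +
    ggplot2::geom_point(data = points[points$kind == "draw", , drop = FALSE],
                        ggplot2::aes(x = .data$x, y = .data$y),
                        color = "grey60", alpha = 0.7) +
    ggplot2::geom_point(data = points[points$kind == "mean", , drop = FALSE],
                        ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 8, size = 3, color = "black") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(title)) gg <- gg + ggplot2::ggtitle(title)
  gg
}
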
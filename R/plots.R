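## Optional figure rendering. Figures are side-effects of the computed
## results (never the data of record); every plot takes a result object.

#' PCA score plot
#'
#' @param pca a `pca_result`.
#' @param components two component indices.
#' @param col optional per-sample colours (defaults to species factor).
#' @return invisibly, the score coordinates plotted.
#' @export
plot_pca_scores <- function(pca, components = c(1, 2), col = NULL) {
  sc <- pca$scores[, components, drop = FALSE]
  v <- pca$explained_variance_pct[components]
  species <- pca$species %||% rep("sample", nrow(sc))
  col <- col %||% as.integer(factor(species)) + 1L
  graphics::plot(sc[, 1], sc[, 2], col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1], v[1]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2], v[2]),
                 main = "PCA of autoscaled abundance matrix")
  graphics::legend("topright", legend = unique(species), pch = 19,
                   col = unique(col), bty = "n", cex = 0.8)
  invisible(sc)
}

#' Sample dendrogram
#'
#' @param hca an `hclust` from [hca_abundance()].
#' @param ... passed to `plot.hclust`.
#' @return invisibly, `hca`.
#' @export
plot_dendrogram <- function(hca, ...) {
  graphics::plot(hca, xlab = "", sub = "",
                 main = "HCA of samples (Euclidean distance)", ...)
  invisible(hca)
}

#' Superclass x replicate heatmap
#'
#' Draws the raw count matrix with the precomputed average-linkage row and
#' column orders of [heatmap_matrix()].
#'
#' @param hm a `heatmap_matrix`.
#' @return invisibly, the reordered count matrix drawn.
#' @export
plot_heatmap_counts <- function(hm) {
  m <- hm$counts[hm$row_order, hm$col_order, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("firebrick", "white", "navy"))(64)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m), col = pal,
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Compounds per superclass and replicate")
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.6)
  invisible(m)
}

#' Pie chart of a species' superclass distribution
#'
#' @param dist a [distribution_table()] data.frame.
#' @param species species column to draw.
#' @return invisibly, the named counts drawn.
#' @export
plot_superclass_pie <- function(dist, species) {
  counts <- stats::setNames(dist[[species]], dist$superclass)
  counts <- counts[counts > 0]
  graphics::pie(counts, main = paste("Superclass distribution:", species),
                cex = 0.7)
  invisible(counts)
}
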
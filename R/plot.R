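# Minimal node-map visualization helper.

#' Plot a ranked node map
#'
#' Draws the nodes of a ranking on a grid (or at supplied coordinates),
#' shading each node by its rank (dark = best-ranked) and optionally
#' starring the top-k nodes and outlining a highlighted label set (e.g. the
#' clinical SOZ).  Optionally overlays the strongest edges of a GC map.
#'
#' @param r a [NodeRanking-class].
#' @param coords optional 2-column matrix of node coordinates (rows in
#'   label order); default lays the nodes out on a square grid.
#' @param g optional [GCMap-class] whose strongest edges to overlay.
#' @param topEdges how many of the largest-weight edges to draw.
#' @param k star the top-k ranked nodes (0 = none).
#' @param highlight character labels to outline (e.g. SOZ nodes).
#' @param ... passed to [graphics::plot()].
#' @return `invisible(NULL)`; draws on the current device.
#' @export
plotNodeMap <- function(r, coords = NULL, g = NULL, topEdges = 20, k = 0,
                        highlight = character(), ...) {
  stopifnot(is(r, "NodeRanking"))
  labs <- nodeLabels(r)
  n <- length(labs)
  if (is.null(coords)) {
    side <- ceiling(sqrt(n))
    coords <- cbind((seq_len(n) - 1) %% side,
                    side - 1 - (seq_len(n) - 1) %/% side)
  }
  ranks <- nodeRanks(r)
  shade <- grDevices::gray(0.15 + 0.75 * (ranks - 1) / max(1, n - 1))
  graphics::plot(coords, pch = 21, bg = shade, cex = 2, axes = FALSE,
                 xlab = "", ylab = "", asp = 1, ...)
  if (!is.null(g)) {
    w <- gcWeights(g)
    idx <- order(w, decreasing = TRUE)[seq_len(min(topEdges, sum(w > 0)))]
    ij <- arrayInd(idx, dim(w))
    graphics::segments(coords[ij[, 1], 1], coords[ij[, 1], 2],
                       coords[ij[, 2], 1], coords[ij[, 2], 2],
                       col = "#00000040")
  }
  if (length(highlight)) {
    hi <- match(intersect(highlight, labs), labs)
    graphics::points(coords[hi, , drop = FALSE], pch = 1, cex = 2.8,
                     col = "red", lwd = 2)
  }
  if (k > 0) {
    top <- match(topK(r, k), labs)
    graphics::points(coords[top, , drop = FALSE], pch = 8, cex = 1.2,
                     col = "gold3")
  }
  invisible(NULL)
}
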
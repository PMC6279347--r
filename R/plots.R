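#' Heatmap of a cross-temporal generalization matrix
#'
#' Base-graphics heatmap with train TR on the y axis, test TR on the x axis,
#' a diverging palette centred on chance, and optional overlay of the
#' significant-cluster mask.
#'
#' @param gm a [GeneralizationMatrix-class] or plain matrix.
#' @param chance centre of the colour scale (default 1/3).
#' @param clusterResult optional [ClusterResult-class]; significant cells are
#'   outlined with points.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the matrix drawn.
#' @export
plotGeneralizationMatrix <- function(gm, chance = 1 / 3,
                                     clusterResult = NULL, ...) {
  m <- if (methods::is(gm, "GeneralizationMatrix")) accuracy(gm)
       else as.matrix(gm)
  lim <- max(abs(range(m, na.rm = TRUE) - chance))
  pal <- grDevices::hcl.colors(65, "Blue-Red 3")
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  zlim = chance + c(-lim, lim), col = pal,
                  xlab = "test TR", ylab = "train TR", ...)
  if (!is.null(clusterResult)) {
    sig <- which(clusterResult@sigMask, arr.ind = TRUE)
    if (nrow(sig))
      graphics::points(sig[, 2], sig[, 1], pch = 0, cex = 1.4)
  }
  invisible(m)
}

#' Scatter plot of classical MDS coordinates of an RDM
#'
#' Categories are colour-coded and relevance levels shape-coded, following
#' the conventional display of category/relevance structure in MDS space.
#'
#' @param rdm an [RDM-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the coordinate matrix.
#' @export
plotMds <- function(rdm, ...) {
  coords <- classicalMds(rdm, k = 2L)
  lab <- rdmLabels(rdm)
  cats <- sort(unique(lab$category))
  rels <- sort(unique(lab$relevance))
  graphics::plot(coords[, 1], coords[, 2],
                 col = match(lab$category, cats),
                 pch = c(15, 17, 19)[match(lab$relevance, rels)],
                 xlab = "dimension 1", ylab = "dimension 2", asp = 1, ...)
  graphics::legend("topright",
                   legend = c(paste("category", cats), as.character(rels)),
                   col = c(seq_along(cats), rep("black", length(rels))),
                   pch = c(rep(15, length(cats)), c(15, 17, 19)[seq_along(rels)]),
                   bty = "n", cex = 0.8)
  invisible(coords)
}
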
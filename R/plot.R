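# Presentation-only rendering of a layout: nodes coloured by module, edges
# as straight gray lines, module regions as rectangles.

#' Plot a grid layout
#'
#' Base-graphics rendering of a node layout: straight gray edges, circles
#' coloured by module, optional module-region rectangles. The y axis is
#' flipped so the drawing matches the screen convention (y grows
#' downward) used by the layout coordinates.
#'
#' @param x a [grid_layout()] over node ids.
#' @param network undirected `igraph` graph with vertex names.
#' @param assignment optional [module_assignment()] used for colours.
#' @param regions optional `module_regions` from [expand_modules()].
#' @param labels draw node labels if `TRUE`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.grid_layout <- function(x, network = NULL, assignment = NULL,
                             regions = NULL, labels = FALSE, ...) {
  pos <- x$pos
  graphics::plot(pos[, 1L], -pos[, 2L], type = "n", asp = 1,
                 xlab = "x", ylab = "-y", ...)
  if (!is.null(regions)) {
    graphics::rect(regions$x0 - 0.5, -(regions$y0 + regions$side - 0.5),
                   regions$x0 + regions$side - 0.5, -(regions$y0 - 0.5),
                   border = "grey60", lty = 2)
  }
  if (!is.null(network)) {
    el <- igraph::as_edgelist(network)
    if (nrow(el) > 0L)
      graphics::segments(pos[el[, 1L], 1L], -pos[el[, 1L], 2L],
                         pos[el[, 2L], 1L], -pos[el[, 2L], 2L],
                         col = "grey70")
  }
  col <- "steelblue"
  if (!is.null(assignment)) {
    mods <- assignment$module_of[rownames(pos)]
    col <- grDevices::rainbow(length(unique(mods)))[as.integer(factor(mods))]
  }
  graphics::points(pos[, 1L], -pos[, 2L], pch = 21, bg = col, cex = 1.2)
  if (labels)
    graphics::text(pos[, 1L], -pos[, 2L], rownames(pos), pos = 3, cex = 0.7)
  invisible(x)
}
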
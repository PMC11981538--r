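#' Plot a food web layered by trophic level
#'
#' Draws the directed web with nodes placed vertically by trophic level
#' (basal nodes at the bottom) and spread horizontally within each level;
#' node colour encodes the category. Undirected webs fall back to a
#' force-directed layout.
#'
#' @param x a [food_web()].
#' @param vertex_size,label_cex plotting sizes passed to igraph.
#' @param ... further arguments passed to [igraph::plot.igraph()].
#' @return invisibly, the layout matrix.
#' @export
plot.food_web <- function(x, vertex_size = 14, label_cex = 0.7, ...) {
  g <- .as_igraph(x)
  pal <- c(producer = "#66a61e", cyanobacteria = "#1b9e77",
           detritus = "#a6761d", animal = "#7570b3")
  cat <- x$nodes$category
  col <- ifelse(is.na(cat), "grey80", pal[cat])
  if (x$directed && !anyNA(cat)) {
    tl <- as.numeric(trophic_levels(x))
    xpos <- numeric(length(tl))
    for (lev in unique(round(tl, 1))) {
      i <- which(round(tl, 1) == lev)
      xpos[i] <- seq(-1, 1, length.out = length(i) + 2)[-c(1, length(i) + 2)]
    }
    layout <- cbind(xpos, tl)
  } else {
    layout <- igraph::layout_with_fr(g)
  }
  igraph::plot.igraph(g, layout = layout, vertex.size = vertex_size,
                      vertex.color = col, vertex.label.cex = label_cex,
                      vertex.label.color = "black",
                      edge.arrow.size = if (x$directed) 0.3 else 0, ...)
  invisible(layout)
}

#' Heat-map of log10 energy fluxes
#'
#' Displays the flux matrix on a base-10 log scale, rows and columns
#' ordered by ascending trophic level; structural zeros are blank.
#'
#' @param x a [energy_fluxes()] result.
#' @param ... unused.
#' @return invisibly, the log10 matrix displayed.
#' @export
plot.flux_model <- function(x, ...) {
  L <- flux_log10(x)
  n <- nrow(L)
  op <- graphics::par(mar = c(1, 8, 8, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(n), seq_len(n), t(L[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(3, at = seq_len(n), labels = colnames(L), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(L)), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  invisible(L)
}
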
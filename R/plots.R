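#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_text labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Scatter plot of an embedding (PCA / MDS)
#'
#' First two axes with unit labels; axis captions carry the proportion of
#' variance (positive eigenvalues).
#'
#' @param object A `pl_embedding`.
#' @param label Draw unit labels? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pl_embedding
#' @export
autoplot.pl_embedding <- function(object, label = TRUE, ...) {
  gl <- glance(object)
  pct <- function(i) sprintf("axis %d (%.1f%%)", i, 100 * gl$prop_variance[i])
  p <- ggplot(as_tibble(object), aes(x = .data$axis1, y = .data$axis2)) +
    geom_point(size = 2) +
    labs(x = pct(1), y = pct(2),
         title = paste(toupper(attr(object, "method")), "embedding")) +
    theme_minimal()
  if (label) p <- p + geom_text(aes(label = .data$unit), vjust = -0.8, size = 3)
  p
}

#' Plot a median-joining haplotype network
#'
#' Deterministic layout (igraph Fruchterman-Reingold under a fixed seed);
#' node area scales with multiplicity, median vectors drawn hollow.
#'
#' @param x An `mj_network`.
#' @param seed Layout seed (default 1).
#' @param ... Passed on to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.mj_network <- function(x, seed = 1, ...) {
  g <- x$graph
  lay <- withr::with_seed(seed, igraph::layout_with_fr(g))
  mult <- igraph::V(g)$multiplicity
  igraph::plot.igraph(
    g, layout = lay,
    vertex.size = 6 + 4 * sqrt(mult),
    vertex.color = ifelse(igraph::V(g)$type == "median", "white", "steelblue"),
    edge.label = x$edges$weight, ...)
  invisible(x)
}

#' Plot a phylogeny with haplogroup node labels
#'
#' Thin wrapper over [ape::plot.phylo()] showing internal haplogroup
#' labels.
#'
#' @param tree A `phylo` (e.g. from [resolve_polytomies()]).
#' @param ... Passed to [ape::plot.phylo()].
#' @return `tree`, invisibly.
#' @export
plot_haplogroup_tree <- function(tree, ...) {
  ape::plot.phylo(tree, ...)
  if (!is.null(tree$node.label)) ape::nodelabels(tree$node.label, frame = "none",
                                                 adj = c(1.1, -0.3), cex = 0.7)
  invisible(tree)
}
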
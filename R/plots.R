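#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_text geom_line
#'   geom_boxplot labs facet_wrap theme_minimal
NULL

#' Scatter plot of an MDS configuration
#'
#' @param object an `ystr_mds`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ystr_mds <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$dim1,
                 y = if ("dim2" %in% names(df)) .data$dim2 else 0)) +
    geom_point() +
    geom_text(aes(label = .data$label), vjust = -0.6, size = 3) +
    labs(x = "Dimension 1", y = "Dimension 2",
         title = sprintf("%s MDS (stress-1 = %.3f%%)",
                         object$method, object$stress)) +
    theme_minimal()
}

#' Rarefaction curves of distinct and private alleles
#'
#' Plots the mean-over-loci expected distinct and private allele counts per
#' population against the standardized subsample size.
#'
#' @param object a `rarefaction_curve` from [richness_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  mv <- attr(object, "mean_over_loci")
  long <- tidyr::pivot_longer(mv, c("distinct", "private"),
                              names_to = "measure", values_to = "alleles")
  ggplot(long, aes(x = .data$g, y = .data$alleles,
                   colour = .data$population)) +
    geom_line() +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = "subsample size g", y = "mean alleles per locus") +
    theme_minimal()
}

#' Box plot of bootstrap F_ST / F_ST^max ratios per population
#'
#' @param object an `fstruct_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fstruct_result <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$population, y = .data$ratio)) +
    geom_boxplot() +
    labs(y = expression(F[ST] / F[ST]^max)) +
    theme_minimal()
}

#' Plot a median-joining network
#'
#' Base-graphics layout via igraph: observed nodes scaled by multiplicity,
#' median vectors drawn small; edge widths shrink with mutational steps.
#'
#' @param x a `haplo_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.haplo_network <- function(x, ...) {
  g <- x$graph
  size <- igraph::V(g)$size
  vs <- ifelse(size > 0, 6 + 4 * sqrt(size), 2)
  col <- ifelse(igraph::V(g)$kind == "median", "grey60", "tomato")
  igraph::plot.igraph(g, vertex.size = vs, vertex.color = col,
                      vertex.label = NA,
                      edge.width = 3 / pmax(1, igraph::E(g)$steps), ...)
  invisible(x)
}

#' Plot a dendrogram
#' @param x an `ystr_dendrogram`.
#' @param ... passed to [plot.hclust()].
#' @export
plot.ystr_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}
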
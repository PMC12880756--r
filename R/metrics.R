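#' Descriptive graph metrics
#'
#' Computes the summary statistics used to characterise contact networks:
#' order, size, density, degree extremes and mean, average local clustering
#' coefficient, degree assortativity, diameter, and the distribution of
#' unordered vertex pairs by shortest-path distance.
#'
#' Density is \eqn{2m / (n(n-1))} and mean degree \eqn{2m/n}.  Clustering is
#' the average of the local clustering coefficients with degree-0/1 vertices
#' contributing 0.  Assortativity is the degree-Pearson correlation.  All
#' values are stored at full precision; round only when reporting.
#'
#' @param g a [rooted_graph].
#' @return an object of class `graph_metrics`: a list with fields `n`, `m`,
#'   `density`, `degree_min`, `degree_mean`, `degree_max`, `clustering`,
#'   `assortativity`, `diameter` (`Inf` when disconnected) and
#'   `distance_pair_counts` (named vector, distance as name, including an
#'   `"Inf"` entry for unreachable pairs when present).
#' @examples
#' g <- make_sea_fan(2, 2)
#' compute_metrics(g)
#' @export
compute_metrics <- function(g) {
  n <- n_vertices(g)
  m <- n_edges(g)
  if (n < 2) stop("density is undefined for graphs with fewer than 2 vertices")
  deg <- igraph::degree(g$graph)
  clustering <- igraph::transitivity(g$graph, type = "localaverage", isolates = "zero")
  assort <- suppressWarnings(igraph::assortativity_degree(g$graph))
  d <- igraph::distances(g$graph)
  ut <- d[upper.tri(d)]
  finite <- ut[is.finite(ut)]
  counts <- table(finite)
  dpc <- as.numeric(counts)
  names(dpc) <- names(counts)
  if (any(!is.finite(ut))) dpc <- c(dpc, "Inf" = sum(!is.finite(ut)))
  diam <- if (any(!is.finite(ut))) Inf else max(ut)
  structure(
    list(
      n = n, m = m,
      density = 2 * m / (n * (n - 1)),
      degree_min = min(deg), degree_mean = 2 * m / n, degree_max = max(deg),
      clustering = clustering,
      assortativity = assort,
      diameter = diam,
      distance_pair_counts = dpc
    ),
    class = "graph_metrics"
  )
}

#' @export
print.graph_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("<graph_metrics> n = %d, m = %d\n", x$n, x$m))
  cat(sprintf("  density       %s\n", format(round(x$density, digits))))
  cat(sprintf("  degree        min %g / mean %s / max %g\n",
              x$degree_min, format(round(x$degree_mean, digits)), x$degree_max))
  cat(sprintf("  clustering    %s\n", format(round(x$clustering, digits))))
  cat(sprintf("  assortativity %s\n", format(round(x$assortativity, digits))))
  cat(sprintf("  diameter      %s\n", format(x$diameter)))
  invisible(x)
}
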
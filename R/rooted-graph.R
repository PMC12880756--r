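#' Rooted graphs
#'
#' A `rooted_graph` is an undirected, unweighted simple graph together with a
#' designated root (outbreak) vertex.  Vertices are identified by character
#' labels; the lexicographic order of labels is the deterministic tie-break
#' order used throughout the package.
#'
#' @param graph an [igraph][igraph::igraph-package] object with a vertex
#'   `name` attribute; must be undirected and simple.
#' @param root character label of the root vertex.
#' @return an object of class `rooted_graph` with components `graph` (the
#'   igraph object), `root`, `vertices` (labels in lexicographic order) and
#'   `adj` (named adjacency list of character vectors).
#' @examples
#' g <- rooted_graph_from_edges(rbind(c("a", "b"), c("b", "c")), root = "a")
#' n_vertices(g)
#' @export
rooted_graph <- function(graph, root) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object")
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  if (any(igraph::which_loop(graph))) stop("graph must have no self-loops")
  if (any(igraph::which_multiple(graph))) {
    warning("duplicate edges collapsed")
    graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = FALSE)
  }
  verts <- sort(igraph::V(graph)$name)
  root <- as.character(root)
  if (length(root) != 1L || !(root %in% verts)) {
    stop(sprintf("root vertex '%s' is not in the graph", root))
  }
  adj <- lapply(verts, function(v) {
    sort(igraph::V(graph)$name[igraph::neighbors(graph, v)])
  })
  names(adj) <- verts
  structure(
    list(graph = graph, root = root, vertices = verts, adj = adj),
    class = "rooted_graph"
  )
}

#' @export
print.rooted_graph <- function(x, ...) {
  cat(sprintf(
    "<rooted_graph> %d vertices, %d edges, root '%s'\n",
    n_vertices(x), n_edges(x), x$root
  ))
  invisible(x)
}

#' Build a rooted graph from an edge matrix
#'
#' @param edges two-column character matrix (or data frame), one edge per row.
#' @param root root vertex label.
#' @param isolated optional extra vertices with no incident edges.
#' @return a [rooted_graph].
#' @export
rooted_graph_from_edges <- function(edges, root, isolated = character(0)) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2])) {
    stop("self-loop in edge list")
  }
  verts <- sort(unique(c(as.vector(edges), as.character(isolated), as.character(root))))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  if (nrow(edges) > 0) {
    # collapse duplicates (either orientation)
    key <- apply(edges, 1, function(e) paste(sort(e), collapse = "\r"))
    edges <- edges[!duplicated(key), , drop = FALSE]
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  rooted_graph(g, root)
}

#' Number of vertices / edges
#' @param g a [rooted_graph].
#' @return an integer.
#' @export
n_vertices <- function(g) length(g$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(g) igraph::ecount(g$graph)

#' Neighbourhood of a vertex
#' @param g a [rooted_graph].
#' @param v vertex label.
#' @return character vector of adjacent vertex labels, in label order.
#' @export
neighbours <- function(g, v) {
  if (!v %in% g$vertices) stop(sprintf("unknown vertex '%s'", v))
  g$adj[[v]]
}

#' Read an edge list from a text file or connection
#'
#' One edge per line as two whitespace-separated vertex labels; lines starting
#' with `#` are comments.  Duplicate edges are collapsed with a warning;
#' self-loops are rejected with the offending line number.
#'
#' @param source file path or connection.
#' @param root root vertex label; must occur in the file unless listed in
#'   `isolated`.
#' @param isolated extra vertices not present in any edge line.
#' @return a [rooted_graph].
#' @export
read_edge_list <- function(source, root, isolated = character(0)) {
  lines <- readLines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  ends <- lapply(lines[keep], function(l) strsplit(trimws(l), "\\s+")[[1]])
  bad <- which(vapply(ends, length, 1L) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("line %d: expected two vertex labels", idx[bad[1]]))
  }
  loops <- which(vapply(ends, function(e) e[1] == e[2], logical(1)))
  if (length(loops) > 0) {
    stop(sprintf("line %d: self-loop on vertex '%s'", idx[loops[1]], ends[[loops[1]]][1]))
  }
  em <- do.call(rbind, ends)
  if (is.null(em)) em <- matrix(character(0), ncol = 2)
  key <- apply(em, 1, function(e) paste(sort(e), collapse = "\r"))
  if (anyDuplicated(key)) warning("duplicate edges collapsed")
  verts <- unique(c(as.vector(em), as.character(isolated)))
  if (!root %in% verts) {
    stop(sprintf("root vertex '%s' does not appear in the edge list", root))
  }
  rooted_graph_from_edges(em, root, isolated = isolated)
}

#' Read / write GraphML
#'
#' The root is stored as a `root` graph attribute on write and recovered from
#' it on read (unless overridden).
#'
#' @param path file path.
#' @param root optional root label overriding the stored attribute.
#' @return `read_graphml` returns a [rooted_graph]; `write_graphml` returns
#'   `path` invisibly.
#' @export
read_graphml <- function(path, root = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(root)) {
    root <- igraph::graph_attr(g, "root")
    if (is.null(root)) stop("no root stored in file; supply `root`")
  }
  rooted_graph(g, root)
}

#' @param g a [rooted_graph].
#' @rdname read_graphml
#' @export
write_graphml <- function(g, path) {
  gg <- igraph::set_graph_attr(g$graph, "root", g$root)
  igraph::write_graph(gg, path, format = "graphml")
  invisible(path)
}

#' Shortest-path distance between two vertices
#'
#' Breadth-first-search distance (number of edges); `Inf` when the vertices
#' lie in different components.
#'
#' @param g a [rooted_graph].
#' @param u,v vertex labels.
#' @return a number (possibly `Inf`).
#' @export
graph_distance <- function(g, u, v) {
  for (x in c(u, v)) {
    if (!x %in% g$vertices) stop(sprintf("unknown vertex '%s'", x))
  }
  as.numeric(igraph::distances(g$graph, v = u, to = v))
}
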
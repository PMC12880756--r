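# Shared fixture builders.  Everything is generated in code; no data files.

# A 9-vertex graph consistent with the worked example: root adjacent to
# A, C, D, H; B adjacent to A and C; E, F, G on a tail behind B.
worked_example_graph <- function() {
  rooted_graph_from_edges(rbind(
    c("r", "A"), c("r", "C"), c("r", "D"), c("r", "H"),
    c("A", "B"), c("C", "B"), c("B", "E"), c("E", "F"), c("F", "G")
  ), root = "r")
}

path_graph <- function(n, root = NULL) {
  v <- sprintf("p%02d", seq_len(n))
  if (is.null(root)) root <- v[1]
  rooted_graph_from_edges(cbind(v[-n], v[-1]), root = root)
}

star_graph <- function(n_leaves, root = "c") {
  rooted_graph_from_edges(cbind("c", sprintf("l%02d", seq_len(n_leaves))), root = root)
}

complete_graph <- function(n, root = NULL) {
  v <- sprintf("k%02d", seq_len(n))
  if (is.null(root)) root <- v[1]
  rooted_graph_from_edges(t(utils::combn(v, 2)), root = root)
}

# Seeded G(n, m) graph rooted at its first vertex.
gnm_graph <- function(n, m, seed) {
  g <- costfire:::with_local_seed(seed, igraph::sample_gnm(n, m))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  rooted_graph(g, "v001")
}

# 24 vertices, 226 edges, diameter 2: K24 minus 50 edges among the first 11
# vertices; every removed pair keeps vertex 12 as a common neighbour.
dense_diameter2_graph <- function() {
  v <- sprintf("v%02d", 1:24)
  edges <- t(utils::combn(v, 2))
  removable <- t(utils::combn(v[1:11], 2))
  drop <- apply(removable[1:50, ], 1, paste, collapse = "|")
  keep <- !(apply(edges, 1, paste, collapse = "|") %in% drop)
  rooted_graph_from_edges(edges[keep, ], root = "v01")
}

# Random rooted tree on n vertices; each vertex gets at most `max_children`
# children when the bound is given.
random_tree <- function(n, seed, max_children = Inf) {
  v <- sprintf("t%02d", seq_len(n))
  edges <- NULL
  costfire:::with_local_seed(seed, {
    child_count <- stats::setNames(rep(0, n), v)
    for (i in 2:n) {
      open_parents <- v[seq_len(i - 1)][child_count[seq_len(i - 1)] < max_children]
      parent <- open_parents[sample.int(length(open_parents), 1)]
      child_count[parent] <- child_count[parent] + 1
      edges <- rbind(edges, c(parent, v[i]))
    }
  })
  rooted_graph_from_edges(edges, root = v[1])
}

# Random connected graph: a random tree plus a few extra edges.
random_connected_graph <- function(n, seed, extra = 2) {
  g <- random_tree(n, seed)
  costfire:::with_local_seed(seed + 1, {
    for (i in seq_len(extra)) {
      pair <- sample(g$vertices, 2)
      if (!pair[2] %in% g$adj[[pair[1]]]) {
        g <- rooted_graph(igraph::add_edges(g$graph, pair), g$root)
      }
    }
  })
  g
}

# Random P4-free (cograph) rooted graph built by random unions and joins.
random_cograph <- function(n, seed) {
  build <- function(labels) {
    if (length(labels) == 1) {
      return(igraph::make_empty_graph(1, directed = FALSE) |>
               igraph::set_vertex_attr("name", value = labels))
    }
    k <- sample.int(length(labels) - 1, 1)
    left <- build(labels[1:k])
    right <- build(labels[(k + 1):length(labels)])
    g <- igraph::disjoint_union(left, right)
    if (stats::runif(1) < 0.6) {  # join
      for (a in igraph::V(left)$name) for (b in igraph::V(right)$name) {
        g <- igraph::add_edges(g, c(a, b))
      }
    }
    g
  }
  g <- costfire:::with_local_seed(seed, build(sprintf("c%02d", seq_len(n))))
  rooted_graph(g, "c01")
}

# An unsatisfiable 2N2P formula on 3 variables: the four clauses exclude all
# eight assignments ((x|x|y), (!x|!x|y) kill y = F; (z|z|!y), (!z|!z|!y)
# kill y = T).
unsat_2n2p_n3 <- function() {
  sat_instance(list(c(1, 1, 2), c(-1, -1, 2), c(3, 3, -2), c(-3, -3, -2)))
}

# Total defence spend of a trace's turns, recomputed against the stored
# turn-start states; returns a vector of per-turn costs.
turn_costs <- function(inst, tr) {
  vapply(seq_along(tr$defences$turns), function(i) {
    d <- tr$defences$turns[[i]]
    if (length(d) == 0) return(0L)
    sum(eval_costs(inst$cost_fn, d, i, tr$states[[i]], inst$graph))
  }, 1L)
}
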
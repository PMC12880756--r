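# Instance generators: Sea Fans, 2N2P-SAT formulas, the SAT-to-Cost-Fire
# hardness reduction, and the random-graph models used in simulations.

#' Sea Fan graphs
#'
#' An (f, l)-Sea Fan is a rooted tree whose root carries `f` isomorphic
#' fronds; each frond is a path of `l` vertices (the first adjacent to the
#' root) whose terminal vertex carries two pendant leaves.  The graph has
#' `f * (l + 2) + 1` vertices.
#'
#' @param f number of fronds (\eqn{\ge 1}).
#' @param l path length of each frond, in vertices (\eqn{\ge 1}).
#' @param root label for the root vertex.
#' @return a [rooted_graph].
#' @examples
#' make_sea_fan(2, 3)  # 11 vertices
#' @export
make_sea_fan <- function(f, l, root = "r") {
  f <- as.integer(f); l <- as.integer(l)
  if (f < 1 || l < 1) stop("f and l must be >= 1")
  edges <- list()
  for (i in seq_len(f)) {
    pv <- sprintf("f%03d.p%03d", i, seq_len(l))
    edges[[length(edges) + 1L]] <- cbind(c(root, pv[-l]), pv)
    leaves <- sprintf("f%03d.%s", i, c("xa", "xb"))
    edges[[length(edges) + 1L]] <- cbind(pv[l], leaves)
  }
  rooted_graph_from_edges(do.call(rbind, edges), root)
}

# Path vertices of frond i in root-to-terminal order, plus its two leaves.
sea_fan_frond <- function(i, l) {
  list(path = sprintf("f%03d.p%03d", i, seq_len(l)),
       leaves = sprintf("f%03d.%s", i, c("xa", "xb")))
}

#' Random 2N2P-SAT instances
#'
#' A 2N2P-SAT formula has 3-literal clauses in which every variable occurs
#' exactly twice positively and twice negatively, forcing the clause count
#' `m = 4 n / 3`.  The sampler distributes the `4n` literal occurrences into
#' the `m` clauses by a seeded random permutation.
#'
#' @param n_vars number of variables; `4 * n_vars` must be divisible by 3.
#' @param seed integer seed.
#' @return an object of class `sat_instance`: list with `n_vars`, `m` and
#'   `clauses`, a list of length-3 integer vectors of signed variable indices
#'   (`+i` for the positive literal of variable `i`, `-i` for the negative).
#' @export
random_2n2p_sat <- function(n_vars, seed) {
  n_vars <- as.integer(n_vars)
  if (n_vars < 1 || (4L * n_vars) %% 3L != 0L) {
    stop("4 * n_vars must be divisible by 3")
  }
  m <- (4L * n_vars) %/% 3L
  occurrences <- c(rep(seq_len(n_vars), each = 2), rep(-seq_len(n_vars), each = 2))
  perm <- with_local_seed(as.integer(seed), sample(occurrences))
  clauses <- split(perm, rep(seq_len(m), each = 3))
  names(clauses) <- NULL
  sat_instance(clauses)
}

#' @param clauses list of length-3 signed integer vectors.
#' @rdname random_2n2p_sat
#' @export
sat_instance <- function(clauses) {
  clauses <- lapply(clauses, as.integer)
  if (any(vapply(clauses, length, 1L) != 3L)) stop("clauses must have 3 literals")
  lits <- unlist(clauses)
  if (any(lits == 0)) stop("variable indices must be non-zero")
  n_vars <- max(abs(lits))
  for (i in seq_len(n_vars)) {
    if (sum(lits == i) != 2L || sum(lits == -i) != 2L) {
      stop(sprintf("variable %d must occur exactly twice positively and twice negatively", i))
    }
  }
  if (length(clauses) != (4L * n_vars) %/% 3L) stop("clause count must be 4n/3")
  structure(list(n_vars = n_vars, m = length(clauses), clauses = clauses),
            class = "sat_instance")
}

#' @export
print.sat_instance <- function(x, ...) {
  cat(sprintf("<sat_instance> %d variables, %d clauses (2N2P)\n", x$n_vars, x$m))
  for (cl in x$clauses) {
    cat("  (", paste(ifelse(cl > 0, paste0("v", cl), paste0("!v", -cl)),
                     collapse = " | "), ")\n", sep = "")
  }
  invisible(x)
}

#' Truth-table satisfiability check
#'
#' Exhaustive check over all `2^n` assignments; the independent oracle for
#' the reduction machinery.
#'
#' @param phi a [sat_instance].
#' @return logical; `TRUE` iff some assignment satisfies every clause.
#' @export
sat_satisfiable <- function(phi) {
  n <- phi$n_vars
  if (n > 20) stop("truth-table check limited to 20 variables")
  for (mask in 0:(2^n - 1)) {
    truth <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    ok <- all(vapply(phi$clauses, function(cl) {
      any((cl > 0) == truth[abs(cl)])
    }, logical(1)))
    if (ok) return(TRUE)
  }
  FALSE
}

#' Reduce a 2N2P-SAT formula to a Cost-Fire instance
#'
#' Builds the hardness-reduction gadget: a `(2n, n + 2m)`-Sea Fan in which
#' frond `i` ends in the positive literal vertex of variable `i` and frond
#' `n + i` in the negative one; each literal vertex's two leaves are labelled
#' with the clauses containing that literal occurrence.  The purely temporal
#' cost function prices, at each time `t <= n`, only the two literal vertices
#' of variable `t` at 2 (budget 2, so exactly one phase can be defended), and
#' at each time `n + j` only the leaves of clause `j` at 1; everything else
#' costs 3 and is unaffordable.  Budget is 2 and the target `k = n + 3m`.
#'
#' @param phi a [sat_instance].
#' @return list with `instance` (a [cost_fire_instance]) and `labels`, a list
#'   mapping literal names (`"v1+"`, `"v1-"`, ...) to literal vertex labels
#'   (`literal_vertices`) and clause ids (`"C1"`, ...) to their three leaf
#'   labels (`clause_leaves`), plus `leaf_parent` (leaf -> literal vertex).
#' @export
reduce_2n2p_to_costfire <- function(phi) {
  stopifnot(inherits(phi, "sat_instance"))
  n <- phi$n_vars; m <- phi$m
  l <- n + 2L * m
  g <- make_sea_fan(2L * n, l)
  literal_vertices <- character(0)
  leaf_clause <- character(0)   # leaf label -> clause id
  leaf_parent <- character(0)   # leaf label -> literal vertex label
  # occurrences of each literal, in clause order
  occ <- function(lit) which(vapply(phi$clauses, function(cl) any(cl == lit), logical(1)))
  for (i in seq_len(n)) {
    for (pol in c(1L, -1L)) {
      frond <- if (pol > 0) i else n + i
      fr <- sea_fan_frond(frond, l)
      lit_name <- sprintf("v%d%s", i, if (pol > 0) "+" else "-")
      lit_vertex <- fr$path[l]
      literal_vertices[lit_name] <- lit_vertex
      cls <- integer(0)
      for (j in seq_along(phi$clauses)) {
        cls <- c(cls, rep(j, sum(phi$clauses[[j]] == pol * i)))
      }
      stopifnot(length(cls) == 2L)
      leaf_clause[fr$leaves] <- sprintf("C%d", cls)
      leaf_parent[fr$leaves] <- lit_vertex
    }
  }
  clause_leaves <- lapply(seq_len(m), function(j) {
    sort(names(leaf_clause)[leaf_clause == sprintf("C%d", j)])
  })
  names(clause_leaves) <- sprintf("C%d", seq_len(m))
  # literal vertex -> variable index it prices at
  lit_time <- stats::setNames(rep(seq_len(n), 2), literal_vertices[
    c(sprintf("v%d+", seq_len(n)), sprintf("v%d-", seq_len(n)))])
  cf <- cost_function("sat_reduction", "purely_temporal",
    eval = function(vertices, time, state, graph) {
      out <- rep(3L, length(vertices))
      if (time <= n) {
        out[vertices %in% names(lit_time)[lit_time == time]] <- 2L
      } else if (time <= n + m) {
        out[vertices %in% clause_leaves[[time - n]]] <- 1L
      }
      out
    })
  inst <- cost_fire_instance(g, cf, budget = 2L, target = n + 3L * m)
  list(
    instance = inst,
    labels = list(literal_vertices = literal_vertices,
                  clause_leaves = clause_leaves,
                  leaf_parent = leaf_parent)
  )
}

#' Random-graph models
#'
#' Seeded generation of the random-graph families used in the simulation
#' study.  The outbreak (root) vertex is drawn uniformly at random unless
#' given.  Vertices are labelled `v001`, `v002`, ... so that label order
#' matches generation order.
#'
#' Models and their `params`:
#' \describe{
#'   \item{`erdos_renyi`}{`n`, `p` -- each pair connected with probability `p`.}
#'   \item{`barabasi_albert`}{`n`, `m` -- preferential attachment, `m` edges
#'     per new vertex.}
#'   \item{`powerlaw_cluster`}{`n`, `m`, `p` -- preferential attachment with a
#'     triangle-closing step taken with probability `p` after each new edge.}
#'   \item{`watts_strogatz`}{`n`, `k`, `p` -- ring lattice on `k` nearest
#'     neighbours (`k` even) with rewiring probability `p`.}
#'   \item{`caveman_connected`}{`cliques`, `size` -- cliques with one edge per
#'     clique rewired to the next clique, forming a central cycle.}
#'   \item{`geometric`}{`n`, `radius` -- uniform points in the unit square,
#'     connected when closer than `radius`.}
#'   \item{`regular`}{`n`, `r` -- uniform random `r`-regular graph
#'     (`n * r` even).}
#' }
#'
#' @param model model name (see Details).
#' @param params named list of model parameters.
#' @param seed integer seed.
#' @param root optional root label; default: uniform random vertex.
#' @return a [rooted_graph].
#' @examples
#' random_graph("erdos_renyi", list(n = 30, p = 0.1), seed = 1)
#' @export
random_graph <- function(model = c("erdos_renyi", "barabasi_albert",
                                   "powerlaw_cluster", "watts_strogatz",
                                   "caveman_connected", "geometric", "regular"),
                         params, seed, root = NULL) {
  model <- match.arg(model)
  seed <- as.integer(seed)
  p <- params
  g <- with_local_seed(seed, switch(model,
    erdos_renyi = igraph::sample_gnp(p$n, p$p),
    barabasi_albert = igraph::sample_pa(p$n, m = p$m, directed = FALSE),
    powerlaw_cluster = powerlaw_cluster_graph(p$n, p$m, p$p),
    watts_strogatz = {
      if (p$k %% 2 != 0) stop("watts_strogatz requires even k")
      igraph::simplify(igraph::sample_smallworld(1, p$n, p$k / 2, p$p))
    },
    caveman_connected = caveman_connected_graph(p$cliques, p$size),
    geometric = igraph::sample_grg(p$n, p$radius),
    regular = {
      if ((p$n * p$r) %% 2 != 0) stop("regular requires n * r even")
      igraph::sample_k_regular(p$n, p$r)
    }
  ))
  n <- igraph::vcount(g)
  igraph::V(g)$name <- sprintf(paste0("v%0", max(3, nchar(n)), "d"), seq_len(n))
  if (is.null(root)) {
    root <- igraph::V(g)$name[keyed_rint(1L, n, seed, "root")]
  }
  rooted_graph(igraph::simplify(g), root)
}

# Holme-Kim clustered power-law graph: preferential attachment on m edges per
# new vertex, closing a triangle with probability p after each attachment.
powerlaw_cluster_graph <- function(n, m, p) {
  if (m < 1 || n < m + 1) stop("require n > m >= 1")
  edges <- integer(0)
  repeated <- rep(seq_len(m), 1)  # degree-weighted target pool, seeded uniform
  for (v in (m + 1):n) {
    targets <- integer(0)
    prev <- NA_integer_
    while (length(targets) < m) {
      close_triangle <- !is.na(prev) && stats::runif(1) < p
      cand <- if (close_triangle) {
        nb <- neighbours_in_edges(edges, prev, v - 1)
        nb <- setdiff(nb, c(v, targets))
        if (length(nb) == 0) pa_pick(repeated, v, targets) else
          nb[sample.int(length(nb), 1)]
      } else {
        pa_pick(repeated, v, targets)
      }
      if (is.na(cand)) break
      targets <- c(targets, cand)
      prev <- cand
    }
    for (t in targets) {
      edges <- c(edges, v, t)
      repeated <- c(repeated, v, t)
    }
  }
  igraph::make_graph(edges, n = n, directed = FALSE)
}

pa_pick <- function(repeated, v, exclude) {
  pool <- setdiff(unique(repeated), c(v, exclude))
  if (length(pool) == 0) return(NA_integer_)
  w <- vapply(pool, function(x) sum(repeated == x), 1L)
  pool[sample.int(length(pool), 1, prob = w)]
}

neighbours_in_edges <- function(edges, v, n_max) {
  if (length(edges) == 0) return(integer(0))
  em <- matrix(edges, ncol = 2, byrow = TRUE)
  unique(c(em[em[, 1] == v, 2], em[em[, 2] == v, 1]))
}

# Connected caveman graph: `cliques` copies of K_size; in each clique one
# edge is removed and replaced by an edge to the next clique, so the
# inter-clique edges form a central cycle.
caveman_connected_graph <- function(cliques, size) {
  if (cliques < 2 || size < 3) stop("require cliques >= 2 and size >= 3")
  edges <- integer(0)
  vid <- function(i, j) (i - 1L) * size + j
  for (i in seq_len(cliques)) {
    for (a in seq_len(size - 1)) for (b in (a + 1):size) {
      if (!(a == 1 && b == 2)) edges <- c(edges, vid(i, a), vid(i, b))
    }
    nxt <- if (i == cliques) 1L else i + 1L
    edges <- c(edges, vid(i, 1), vid(nxt, 2))
  }
  igraph::make_graph(edges, n = cliques * size, directed = FALSE)
}
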
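# Exact and closed-form solvers: a brute-force optimal-play oracle, the
# complete-graph greedy, the bounded-path-length sequence enumeration, the
# Pathcontainable-tree path strategy, the Sea Fan closed form, and the exact
# decision procedure for SAT-reduction instances.

#' Solver results
#'
#' @param max_saved optimal (or best-found) number of saved vertices.
#' @param strat the [strategy] witnessing it.
#' @param method solver tag.
#' @param ... extra fields stored on the result.
#' @return an object of class `solve_result`.
#' @export
solve_result <- function(max_saved, strat, method, ...) {
  structure(list(max_saved = as.integer(max_saved), strategy = strat,
                 method = method, ...),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result> max_saved = %d (method: %s)\n", x$max_saved, x$method))
  invisible(x)
}

# All subsets of `cand` whose summed costs stay within `budget`, the empty
# set included.  Candidates are scanned cheapest-first so the recursion can
# cut off as soon as nothing further fits.
affordable_subsets <- function(cand, costs, budget) {
  ord <- order(costs, cand)
  cand <- cand[ord]; costs <- costs[ord]
  out <- list()
  rec <- function(i, chosen, remaining) {
    out[[length(out) + 1L]] <<- chosen
    if (i > length(cand)) return()
    for (j in i:length(cand)) {
      if (costs[j] > remaining) break
      rec(j + 1L, c(chosen, cand[j]), remaining - costs[j])
    }
  }
  rec(1L, character(0), budget)
  out
}

#' Brute-force optimal play
#'
#' Exhaustive game-tree search: at every turn, all affordable subsets of the
#' open vertices are tried (not only maximal ones -- with state-dependent
#' costs, defending more now can raise prices later).  States are memoised on
#' (burning set, defended set), with the turn number added to the key for
#' time-dependent cost families.  The independent oracle for every other
#' solver.
#'
#' @param inst a [cost_fire_instance].
#' @param size_cap refuse graphs larger than this (default 12); the search
#'   is exponential.
#' @param prune_adjacent restrict candidate defences to open vertices
#'   adjacent to fire.  Lossless for unit-cost, budget-1 play on trees
#'   (where an optimal strategy defends next to the fire), and much faster;
#'   not valid in general, hence off by default.
#' @return a [solve_result] whose strategy replays to exactly `max_saved`.
#' @export
brute_force_optimal <- function(inst, size_cap = 12, prune_adjacent = FALSE) {
  g <- inst$graph
  n <- n_vertices(g)
  if (n > size_cap) {
    stop(sprintf("graph has %d vertices, above the size cap %d", n, size_cap))
  }
  verts <- g$vertices
  idx <- stats::setNames(seq_len(n), verts)
  adj_idx <- lapply(g$adj, function(nb) unname(idx[nb]))
  bit <- 2^(seq_len(n) - 1)
  temporal <- inst$cost_fn$kind %in% c("purely_temporal", "temporally_state_dependent")
  memo <- new.env(parent = emptyenv())

  rec <- function(burning, defended, time) {
    frontier <- unique(unlist(adj_idx[burning], use.names = FALSE))
    open_adj <- frontier[!burning[frontier] & !defended[frontier]]
    if (length(open_adj) == 0) {
      return(list(saved = n - sum(burning), turns = list()))
    }
    key <- paste(sum(bit[burning]), sum(bit[defended]),
                 if (temporal) time else -1L, sep = ":")
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    status <- stats::setNames(rep("open", n), verts)
    status[burning] <- "burning"
    status[defended] <- "defended"
    s <- game_state(time, status)
    turn <- time + 1L
    cand <- if (prune_adjacent) sort(verts[open_adj]) else
      verts[!burning & !defended]
    costs <- eval_costs(inst$cost_fn, cand, turn, s, g)
    best <- NULL
    for (S in affordable_subsets(cand, costs, inst$budget)) {
      d2 <- defended
      d2[idx[S]] <- TRUE
      b2 <- burning
      ignite <- open_adj[!d2[open_adj]]
      b2[ignite] <- TRUE
      sub <- rec(b2, d2, time + 1L)
      if (is.null(best) || sub$saved > best$saved) {
        best <- list(saved = sub$saved, turns = c(list(S), sub$turns))
      }
    }
    assign(key, best, envir = memo)
    best
  }

  burning <- defended <- rep(FALSE, n)
  burning[idx[g$root]] <- TRUE
  res <- rec(burning, defended, 0L)
  solve_result(res$saved, strategy(res$turns), "brute_force")
}

#' Solve Cost-Fire when the root sees every vertex
#'
#' When the root is adjacent to all other vertices (complete graphs, stars
#' rooted at the centre), any vertex not defended in turn 1 burns in turn 1,
#' so the optimum is the single-turn greedy: defend vertices in order of
#' increasing turn-1 cost until the budget runs out.
#'
#' @param inst a [cost_fire_instance] whose root neighbours every vertex.
#' @return a [solve_result].
#' @export
solve_complete <- function(inst) {
  g <- inst$graph
  non_root <- setdiff(g$vertices, g$root)
  non_adj <- setdiff(non_root, g$adj[[g$root]])
  if (length(non_adj) > 0) {
    stop(sprintf("vertex '%s' is not adjacent to the root", non_adj[1]))
  }
  if (length(non_root) == 0) {
    return(solve_result(0L, strategy(), "complete"))
  }
  s0 <- initial_state(g)
  costs <- eval_costs(inst$cost_fn, non_root, 1L, s0, g)
  ord <- order(costs, non_root)
  afford <- cumsum(costs[ord]) <= inst$budget
  chosen <- non_root[ord][afford]
  strat <- if (length(chosen) > 0) strategy(list(chosen)) else strategy()
  solve_result(length(chosen), strat, "complete")
}

#' Closed-form Sea Fan optimum for classic Fire
#'
#' The maximum number of vertices saved by budget-1, unit-cost play on an
#' (f, l)-Sea Fan with the fire starting at the root:
#' \deqn{f(2l + 5 - f)/2 \textrm{ if } f \le l, \qquad l(l+5)/2 + 1 \textrm{ otherwise.}}
#' One frond is sealed per turn, at increasing depth, until either every
#' frond is entered (f <= l) or the fire outruns the defender (f > l).
#'
#' @param f number of fronds (\eqn{\ge 1}).
#' @param l frond path length in vertices (\eqn{\ge 1}).
#' @return integer, the maximum number of saved vertices.
#' @examples
#' sea_fan_fire_max_saved(1, 1)  # 3
#' @export
sea_fan_fire_max_saved <- function(f, l) {
  f <- as.integer(f); l <- as.integer(l)
  if (f < 1 || l < 1) stop("f and l must be >= 1")
  if (f <= l) as.integer(f * (2 * l + 5 - f) / 2) else
    as.integer(l * (l + 5) / 2 + 1)
}

#' Solve Cost-Fire on graphs with no long induced path
#'
#' On a graph with no induced path on `l` vertices the game lasts at most
#' `l - 2` turns, so an optimal strategy defends at most `b (l - 2)`
#' vertices.  All ordered sequences of distinct non-root vertices up to that
#' length are enumerated; each sequence is simulated by scanning its
#' remaining entries in order every turn -- burning entries are discarded
#' permanently, affordable open entries defended, unaffordable ones retained
#' for later turns.  Outcomes are validated by a depth-first search from the
#' root over the undefended graph, counting unburned vertices.
#'
#' @param inst a [cost_fire_instance] on a `Pl`-free graph (caller-asserted).
#' @param l the excluded induced-path length in vertices (\eqn{\ge 2}).
#' @return a [solve_result].
#' @export
solve_pl_free <- function(inst, l) {
  l <- as.integer(l)
  if (l < 2) stop("require l >= 2")
  g <- inst$graph
  max_len <- inst$budget * (l - 2L)
  non_root <- setdiff(g$vertices, g$root)
  best <- list(saved = -1L, turns = list())

  simulate <- function(seqq) {
    s <- initial_state(g)
    turns <- list()
    pending <- seqq
    turn <- 0L
    while (!is_contained(g, s)) {
      turn <- turn + 1L
      pending <- pending[s$status[pending] != "burning"]
      chosen <- character(0)
      remaining <- inst$budget
      if (length(pending) > 0) {
        costs <- eval_costs(inst$cost_fn, pending, turn, s, g)
        for (i in seq_along(pending)) {
          if (costs[i] <= remaining) {
            chosen <- c(chosen, pending[i])
            remaining <- remaining - costs[i]
          }
        }
      }
      pending <- setdiff(pending, chosen)
      s <- apply_turn(g, s, chosen, inst$cost_fn, inst$budget, turn)
      turns[[turn]] <- chosen
    }
    defended <- names(s$status)[s$status == "defended"]
    residual <- igraph::delete_vertices(g$graph, defended)
    burned <- length(igraph::subcomponent(residual, g$root))
    list(saved = n_vertices(g) - burned, turns = turns)
  }

  explore <- function(seqq) {
    res <- simulate(seqq)
    if (res$saved > best$saved) best <<- res
    if (length(seqq) < max_len) {
      for (v in setdiff(non_root, seqq)) explore(c(seqq, v))
    }
  }
  explore(character(0))
  solve_result(best$saved, strategy(best$turns), "pl_free")
}

#' Check the Pathcontainable properties
#'
#' A tree instance is Pathcontainable when (1) an open vertex next to the
#' fire never costs more than an open vertex away from it, and (2) for every
#' burning vertex with `x` open neighbours, every subset of `x - 1` of them
#' is affordable.  Property 2 reduces to: the summed cost of the open
#' neighbours minus the cheapest one is within budget.
#'
#' Modes: `"trace"` checks both properties at every state of a supplied
#' trace; `"exhaustive"` enumerates every connected burning set containing
#' the root (trees up to `size_cap` vertices; defences empty, the turn taken
#' as the earliest the set is reachable); `"declared"` records a caller
#' assertion.
#'
#' @param inst a [cost_fire_instance].
#' @param mode `"trace"`, `"exhaustive"` or `"declared"`.
#' @param trace a [trace] (required for `mode = "trace"`).
#' @param size_cap vertex bound for exhaustive mode.
#' @return an object of class `pathcontainable_report`: list with `property1`
#'   and `property2` (each `status` `"holds"`/`"fails"`/`"declared"` plus a
#'   `witness` description on failure) and `mode`.
#' @export
check_pathcontainable <- function(inst, mode = c("trace", "exhaustive", "declared"),
                                  trace = NULL, size_cap = 12) {
  mode <- match.arg(mode)
  g <- inst$graph
  p1 <- list(status = "holds", witness = NULL)
  p2 <- list(status = "holds", witness = NULL)

  check_state <- function(s) {
    turn <- s$time + 1L
    open <- open_vertices(s)
    burning <- burning_vertices(s)
    if (length(open) > 0) {
      near <- open[vapply(open, function(v) any(s$status[g$adj[[v]]] == "burning"),
                          logical(1))]
      far <- setdiff(open, near)
      if (length(near) > 0 && length(far) > 0 && p1$status == "holds") {
        costs <- stats::setNames(eval_costs(inst$cost_fn, open, turn, s, g), open)
        if (max(costs[near]) > min(costs[far])) {
          p1 <<- list(status = "fails", witness = sprintf(
            "at time %d, fire-adjacent '%s' costs %d > %d for distant '%s'",
            s$time, near[which.max(costs[near])], max(costs[near]),
            min(costs[far]), far[which.min(costs[far])]))
        }
      }
    }
    for (v in burning) {
      if (p2$status != "holds") break
      nb_open <- g$adj[[v]][s$status[g$adj[[v]]] == "open"]
      if (length(nb_open) >= 2) {
        costs <- eval_costs(inst$cost_fn, nb_open, turn, s, g)
        if (sum(costs) - min(costs) > inst$budget) {
          p2 <<- list(status = "fails", witness = sprintf(
            "at time %d, burning '%s' has %d open neighbours; dearest %d of them cost %d > budget %d",
            s$time, v, length(nb_open), length(nb_open) - 1L,
            sum(costs) - min(costs), inst$budget))
        }
      }
    }
  }

  if (mode == "trace") {
    if (is.null(trace)) stop("trace mode requires a trace")
    for (s in trace$states) check_state(s)
  } else if (mode == "exhaustive") {
    if (!igraph::is_tree(g$graph)) stop("exhaustive mode requires a tree")
    n <- n_vertices(g)
    if (n > size_cap) {
      stop(sprintf("graph has %d vertices, above the size cap %d", n, size_cap))
    }
    others <- setdiff(g$vertices, g$root)
    d_root <- igraph::distances(g$graph, v = g$root)[1, ]
    for (mask in 0:(2^length(others) - 1)) {
      inc <- bitwAnd(mask, 2^(seq_along(others) - 1)) > 0
      B <- c(g$root, others[inc])
      if (length(B) < n &&
          !igraph::is_connected(igraph::induced_subgraph(g$graph, B))) next
      status <- stats::setNames(rep("open", n), g$vertices)
      status[B] <- "burning"
      check_state(game_state(max(d_root[B]), status))
      if (p1$status == "fails" && p2$status == "fails") break
    }
  } else {
    p1 <- p2 <- list(status = "declared", witness = NULL)
  }
  structure(list(property1 = p1, property2 = p2, mode = mode),
            class = "pathcontainable_report")
}

#' @export
print.pathcontainable_report <- function(x, ...) {
  cat(sprintf("<pathcontainable_report> (%s mode)\n", x$mode))
  for (p in c("property1", "property2")) {
    cat(sprintf("  %s: %s%s\n", p, x[[p]]$status,
                if (is.null(x[[p]]$witness)) "" else paste0(" -- ", x[[p]]$witness)))
  }
  invisible(x)
}

#' Solve Pathcontainable Cost-Fire instances on trees
#'
#' Under the Pathcontainable properties an optimal play burns only a shortest
#' path from the root to the nearest *defensible* vertex -- one whose open
#' neighbours can all be afforded when the fire reaches it.  Vertices are
#' scanned in breadth-first order (distance, then label); for each candidate
#' the path strategy is simulated: every turn, all open neighbours of the
#' newest burning path vertex except the next path vertex are defended, and
#' at the candidate itself all its open neighbours.  The first candidate
#' whose simulation respects the budget wins.
#'
#' The winning trace is re-checked in trace mode against the Pathcontainable
#' properties; a violation sets `flagged = TRUE` on the result (optimality is
#' then not guaranteed).
#'
#' @param inst a [cost_fire_instance] on a tree.
#' @return a [solve_result] with extra fields `pathcontainable` (the
#'   [check_pathcontainable()] report) and `flagged`.
#' @export
solve_pathcontainable_tree <- function(inst) {
  g <- inst$graph
  if (!igraph::is_tree(g$graph)) stop("instance is not on a tree")
  d_root <- igraph::distances(g$graph, v = g$root)[1, g$vertices]
  candidates <- g$vertices[order(d_root, g$vertices)]
  for (v in candidates) {
    sim <- simulate_path_strategy(inst, v)
    if (!is.null(sim)) {
      tr <- play(inst, sim)
      report <- check_pathcontainable(inst, mode = "trace", trace = tr)
      flagged <- report$property1$status == "fails" ||
        report$property2$status == "fails"
      return(solve_result(count_saved(tr), sim, "pathcontainable_tree",
                          target_vertex = v, pathcontainable = report,
                          flagged = flagged))
    }
  }
  stop("no vertex is defensible within budget")
}

# Simulate burning the root-to-v path, defending all other neighbours of the
# newest burning path vertex each turn.  Returns the strategy, or NULL if a
# turn's defences exceed the budget.
simulate_path_strategy <- function(inst, v) {
  g <- inst$graph
  path <- names(igraph::shortest_paths(g$graph, from = g$root, to = v)$vpath[[1]])
  s <- initial_state(g)
  turns <- list()
  for (t in seq_along(path)) {
    if (is_contained(g, s)) break
    def <- g$adj[[path[t]]][s$status[g$adj[[path[t]]]] == "open"]
    if (t < length(path)) def <- setdiff(def, path[t + 1])
    step <- apply_turn(g, s, def, inst$cost_fn, inst$budget, t, on_violation = "flag")
    if (length(step$violations) > 0) return(NULL)
    s <- step$state
    turns[[t]] <- def
  }
  if (!is_contained(g, s)) return(NULL)
  strategy(turns)
}

#' Decide a SAT-reduction Cost-Fire instance exactly
#'
#' For instances produced by [reduce_2n2p_to_costfire()] the cost function
#' leaves, at each time `t <= n`, only the two literal vertices of variable
#' `t` affordable (cost 2 against budget 2, so at most one), and at each time
#' `n + j` only the leaves of clause `j` (cost 1, so at most two).  The
#' procedure searches the `3^n` per-variable phase choices, completes each
#' with the greedy clause phase (defend up to two still-at-risk leaves of the
#' turn's clause), replays every candidate through the game engine, and
#' reports whether the target `k = n + 3m` is reached.
#'
#' @param phi a [sat_instance].
#' @return list with `decision` (logical), `result` (the best
#'   [solve_result]) and `instance` (the reduced [cost_fire_instance]).
#' @export
decide_reduced_instance <- function(phi) {
  red <- reduce_2n2p_to_costfire(phi)
  inst <- red$instance
  lab <- red$labels
  n <- phi$n_vars; m <- phi$m
  best <- NULL
  for (code in 0:(3^n - 1)) {
    a <- (code %/% 3^(seq_len(n) - 1)) %% 3  # 0 = none, 1 = positive, 2 = negative
    turns <- vector("list", n + m)
    for (t in seq_len(n)) {
      turns[[t]] <- switch(a[t] + 1,
        character(0),
        unname(lab$literal_vertices[sprintf("v%d+", t)]),
        unname(lab$literal_vertices[sprintf("v%d-", t)]))
    }
    defended_lits <- unlist(turns[seq_len(n)])
    for (j in seq_len(m)) {
      leaves <- lab$clause_leaves[[sprintf("C%d", j)]]
      at_risk <- leaves[!(lab$leaf_parent[leaves] %in% defended_lits)]
      turns[[n + j]] <- utils::head(at_risk, 2)
    }
    tr <- play(inst, strategy(turns))
    if (tr$valid && (is.null(best) || count_saved(tr) > best$saved)) {
      best <- list(saved = count_saved(tr), turns = turns)
    }
  }
  res <- solve_result(best$saved, strategy(best$turns), "sat_reduction")
  list(decision = best$saved >= inst$target, result = res, instance = inst)
}
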
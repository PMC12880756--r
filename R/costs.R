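# Cost-function families.
#
# A cost function maps (vertex, turn, game state) to a positive integer, the
# price of defending that vertex this turn.  Families are classified by what
# the price may depend on: static (vertex only), purely temporal (vertex and
# turn), purely state-dependent (vertex and state) or temporally
# state-dependent (all three).  Costs are recomputed at the start of every
# turn and frozen for that turn.

#' Cost functions
#'
#' Constructor for cost-function objects.  Most users want one of the
#' built-in families: [uniform_cost()], [random_preference()],
#' [burning_neighbours()], [distance_from_fire()], [periodic_cost()],
#' [binary_hesitation()], [threat_stochastic()].
#'
#' @param family short family tag (used in reports and spec strings).
#' @param kind one of `"static"`, `"purely_temporal"`,
#'   `"purely_state_dependent"`, `"temporally_state_dependent"`.
#' @param eval function `(vertices, time, state, graph)` returning one
#'   integer cost \eqn{\ge 1} per vertex.
#' @param seed optional integer seed for stochastic families.
#' @return an object of class `cost_function`.
#' @export
cost_function <- function(family, kind, eval, seed = NULL) {
  kind <- match.arg(kind, c("static", "purely_temporal",
                            "purely_state_dependent", "temporally_state_dependent"))
  structure(list(family = family, kind = kind, eval = eval, seed = seed),
            class = "cost_function")
}

#' @export
print.cost_function <- function(x, ...) {
  cat(sprintf("<cost_function> %s (%s)%s\n", x$family, x$kind,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Evaluate defence costs
#'
#' Applies a cost function to a set of vertices at a given turn and state and
#' validates the contract: every returned cost is an integer \eqn{\ge 1}.
#'
#' @param cost_fn a [cost_function].
#' @param vertices character vector of vertex labels.
#' @param time turn number at which the defence would be placed.
#' @param state the turn-start [game_state] (at `time - 1`).
#' @param graph the [rooted_graph].
#' @return integer vector of costs, one per vertex.
#' @export
eval_costs <- function(cost_fn, vertices, time, state, graph) {
  if (length(vertices) == 0) return(integer(0))
  out <- cost_fn$eval(vertices, time, state, graph)
  if (length(out) != length(vertices) || any(is.na(out)) ||
      any(out < 1) || any(out != round(out))) {
    stop(sprintf("cost function '%s' must return one integer >= 1 per vertex",
                 cost_fn$family))
  }
  as.integer(out)
}

# Distance from each vertex to the nearest burning vertex, capped at the
# graph order n for vertices no fire can reach.
dist_to_fire <- function(graph, state, vertices) {
  burning <- names(state$status)[state$status == "burning"]
  n <- n_vertices(graph)
  if (length(burning) == 0) return(stats::setNames(rep(n, length(vertices)), vertices))
  d <- igraph::distances(graph$graph, v = burning, to = vertices)
  out <- apply(d, 2, min)
  out[!is.finite(out)] <- n
  stats::setNames(as.numeric(out), vertices)
}

#' Uniform cost
#'
#' Every vertex costs 1 at all times; with budget \eqn{b} this recovers
#' b-Fire, and with budget 1 the classic Firefighter game.
#'
#' @return a static [cost_function].
#' @export
uniform_cost <- function() {
  cost_function("uniform", "static", function(vertices, time, state, graph) {
    rep(1L, length(vertices))
  })
}

#' Randomised individual preference
#'
#' Each vertex is assigned, once and for all, a cost drawn uniformly from
#' \{1, ..., 5\}; the cost never changes as the game progresses.
#'
#' @param seed integer seed; the same seed yields the same cost map.
#' @return a static [cost_function].
#' @export
random_preference <- function(seed) {
  stopifnot(!missing(seed))
  seed <- as.integer(seed)
  cost_function("random_pref", "static", seed = seed,
    eval = function(vertices, time, state, graph) {
      vapply(vertices, function(v) keyed_rint(1L, 5L, seed, "random_pref", v), 1)
    })
}

#' Burning-neighbours cost
#'
#' Cost of a vertex is \eqn{\max(b - f_{v,t}, 1)} where \eqn{f_{v,t}} is its
#' number of burning neighbours: the more infected contacts, the cheaper the
#' defence.
#'
#' @param b the budget the costs are anchored to (\eqn{\ge 1}).
#' @return a purely state-dependent [cost_function].
#' @export
burning_neighbours <- function(b) {
  b <- as.integer(b)
  if (b < 1) stop("b must be >= 1")
  cost_function("burning_nbrs", "purely_state_dependent",
    eval = function(vertices, time, state, graph) {
      f <- vapply(vertices, function(v) {
        sum(state$status[graph$adj[[v]]] == "burning")
      }, 1L)
      pmax(b - f, 1L)
    })
}

#' Distance-from-fire cost
#'
#' Cost of a vertex is its shortest-path distance to the nearest burning
#' vertex; vertices in a fire-free component get the cap `n` (the graph
#' order), a finite stand-in for an infinite distance.
#'
#' @return a purely state-dependent [cost_function].
#' @export
distance_from_fire <- function() {
  cost_function("dist_fire", "purely_state_dependent",
    eval = function(vertices, time, state, graph) {
      pmax(dist_to_fire(graph, state, vertices), 1)
    })
}

#' Periodic (seasonal) cost
#'
#' Cost is 2 on even turns and 1 on odd turns: every second turn, defence is
#' twice as expensive everywhere.
#'
#' @return a purely temporal [cost_function].
#' @export
periodic_cost <- function() {
  cost_function("periodic", "purely_temporal",
    eval = function(vertices, time, state, graph) {
      rep(if (time %% 2 == 0) 2L else 1L, length(vertices))
    })
}

#' Binary hesitation cost
#'
#' Each vertex, independently at every turn, costs 2 with probability 0.297
#' and 1 otherwise (mirroring an empirical vaccine-hesitancy rate).  Draws
#' are keyed on (seed, vertex, turn), so a given seed fixes the whole cost
#' surface.
#'
#' @param seed integer seed.
#' @return a temporally state-independent, per-turn stochastic
#'   [cost_function] (classified purely temporal).
#' @export
binary_hesitation <- function(seed) {
  stopifnot(!missing(seed))
  seed <- as.integer(seed)
  cost_function("hesitation", "purely_temporal", seed = seed,
    eval = function(vertices, time, state, graph) {
      vapply(vertices, function(v) {
        if (keyed_runif(seed, "hesitation", v, time) < 0.297) 2L else 1L
      }, 1L)
    })
}

#' Stochastic threat cost
#'
#' Cost is the distance to the nearest fire plus integer noise drawn
#' uniformly from \eqn{[-3, 3]} (`spread = "high"`) or \eqn{[-1, 1]}
#' (`spread = "low"`), clamped below at 1 since costs are strictly positive.
#'
#' @param spread `"high"` or `"low"` noise amplitude.
#' @param seed integer seed; noise is keyed on (seed, vertex, turn).
#' @return a temporally state-dependent [cost_function].
#' @export
threat_stochastic <- function(spread = c("high", "low"), seed) {
  spread <- match.arg(spread)
  stopifnot(!missing(seed))
  seed <- as.integer(seed)
  amp <- if (spread == "high") 3L else 1L
  cost_function(paste0("threat_stoch_", spread), "temporally_state_dependent",
    seed = seed,
    eval = function(vertices, time, state, graph) {
      d <- dist_to_fire(graph, state, vertices)
      noise <- vapply(vertices, function(v) {
        keyed_rint(-amp, amp, seed, "threat_stoch", v, time)
      }, 1)
      pmax(d + noise, 1)
    })
}
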
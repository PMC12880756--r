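# Budgeted greedy defence heuristics.
#
# Each turn the heuristic ranks the open vertices (random order, highest
# degree first, closest to fire first, or cheapest first), optionally breaks
# ties with a second criterion, and scans the ranking greedily: every vertex
# whose turn-start cost fits the remaining budget is defended; unaffordable
# vertices are skipped, and the scan continues until no open vertex fits.

#' Heuristic specifications
#'
#' @param primary one of `"random"`, `"degree"`, `"threat"`, `"cost"`.
#' @param tiebreak secondary criterion, one of `"none"`, `"degree"`,
#'   `"threat"`, `"cost"`; must differ from `primary`, and must be `"none"`
#'   when `primary = "random"`.
#' @param seed integer seed (required for `primary = "random"`).
#' @return an object of class `heuristic_spec`.
#' @examples
#' heuristic_spec("cost", tiebreak = "threat")
#' @export
heuristic_spec <- function(primary = c("random", "degree", "threat", "cost"),
                           tiebreak = "none", seed = NULL) {
  primary <- match.arg(primary)
  tiebreak <- match.arg(tiebreak, c("none", "degree", "threat", "cost"))
  if (tiebreak == primary) stop("tiebreak must differ from the primary heuristic")
  if (primary == "random") {
    if (tiebreak != "none") stop("random primary takes no tiebreak")
    if (is.null(seed)) stop("random primary requires a seed")
  }
  structure(list(primary = primary, tiebreak = tiebreak,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "heuristic_spec")
}

#' @export
print.heuristic_spec <- function(x, ...) {
  cat(sprintf("<heuristic_spec> %s%s%s\n", x$primary,
              if (x$tiebreak == "none") "" else paste0(" / tiebreak ", x$tiebreak),
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  invisible(x)
}

#' Score open vertices for a defence heuristic
#'
#' Scores are oriented so that smaller means defended earlier: degree scores
#' are negated degrees, threat is the distance to the nearest burning vertex
#' (capped at the graph order for unreachable vertices), and cost is the
#' supplied per-vertex cost.
#'
#' @param g a [rooted_graph].
#' @param s the turn-start [game_state].
#' @param costs named integer vector of turn-start costs covering all open
#'   vertices.
#' @param kind `"degree"`, `"threat"` or `"cost"`.
#' @return named numeric vector over the open vertices.
#' @export
score_vertices <- function(g, s, costs, kind = c("degree", "threat", "cost")) {
  kind <- match.arg(kind)
  open <- open_vertices(s)
  switch(kind,
    degree = -igraph::degree(g$graph, open),
    threat = dist_to_fire(g, s, open),
    cost = {
      if (!all(open %in% names(costs))) stop("costs must cover all open vertices")
      stats::setNames(as.numeric(costs[open]), open)
    }
  )
}

#' Select a turn's defences under a heuristic
#'
#' Open vertices are considered in (primary score, tiebreak score, label)
#' order -- or in a seed-determined shuffled order for the random heuristic --
#' and each vertex whose turn-start cost fits the remaining budget is added;
#' unaffordable vertices are skipped and the scan continues until no open
#' vertex fits.  The returned set satisfies the budget constraint by
#' construction.
#'
#' @param g a [rooted_graph].
#' @param s the turn-start [game_state] (time `turn - 1`).
#' @param cost_fn a [cost_function].
#' @param budget per-turn budget (0 yields the empty set).
#' @param spec a [heuristic_spec].
#' @param turn positive integer turn number.
#' @return character vector of vertices to defend this turn.
#' @export
select_defences <- function(g, s, cost_fn, budget, spec, turn) {
  open <- open_vertices(s)
  if (length(open) == 0 || budget < 1) return(character(0))
  costs <- stats::setNames(eval_costs(cost_fn, open, turn, s, g), open)
  ord <- if (spec$primary == "random") {
    open[keyed_shuffle(length(open), spec$seed, "heuristic_random", turn)]
  } else {
    primary <- score_vertices(g, s, costs, spec$primary)[open]
    tiebreak <- if (spec$tiebreak == "none") rep(0, length(open)) else
      score_vertices(g, s, costs, spec$tiebreak)[open]
    open[order(primary, tiebreak, open)]
  }
  chosen <- character(0)
  remaining <- budget
  for (v in ord) {
    if (costs[[v]] <= remaining) {
      chosen <- c(chosen, v)
      remaining <- remaining - costs[[v]]
    }
  }
  chosen
}

#' Play a full game under a heuristic
#'
#' Runs [select_defences()] each turn and feeds the result through the game
#' engine until containment.
#'
#' @param inst a [cost_fire_instance].
#' @param spec a [heuristic_spec].
#' @return a [trace].
#' @export
play_heuristic <- function(inst, spec) {
  g <- inst$graph
  s <- initial_state(g)
  turns <- list()
  turn <- 0L
  while (!is_contained(g, s)) {
    turn <- turn + 1L
    defence <- select_defences(g, s, inst$cost_fn, inst$budget, spec, turn)
    turns[[turn]] <- defence
    s <- apply_turn(g, s, defence, inst$cost_fn, inst$budget, turn)
  }
  play(inst, strategy(turns))
}
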
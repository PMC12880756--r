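# The Cost-Fire state machine.
#
# A game proceeds in turns.  At the start of turn i the state carried over
# from turn i-1 is frozen; defence costs are evaluated against that state;
# the turn's defences are validated (each defended vertex open, total cost
# within budget) and applied; then fire spreads: every open vertex adjacent
# to a burning vertex ignites.  Once burning or defended, a vertex never
# changes state.  The game ends when no open vertex is adjacent to fire; all
# unburned vertices are then saved.

#' Game states
#'
#' A snapshot of the game: a time step and an assignment of `"open"`,
#' `"burning"` or `"defended"` to every vertex.
#'
#' @param time non-negative integer time step.
#' @param status named character vector over all vertices with values
#'   `"open"`, `"burning"` or `"defended"`.
#' @return an object of class `game_state`.
#' @export
game_state <- function(time, status) {
  stopifnot(time >= 0, all(status %in% c("open", "burning", "defended")))
  structure(list(time = as.integer(time), status = status), class = "game_state")
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf(
    "<game_state> t = %d | burning: %s | defended: %s\n",
    x$time,
    paste(burning_vertices(x), collapse = ","),
    paste(defended_vertices(x), collapse = ",")
  ))
  invisible(x)
}

#' Vertices in a given state
#' @param s a [game_state].
#' @return character vector of vertex labels, in label order.
#' @export
burning_vertices <- function(s) sort(names(s$status)[s$status == "burning"])

#' @rdname burning_vertices
#' @export
defended_vertices <- function(s) sort(names(s$status)[s$status == "defended"])

#' @rdname burning_vertices
#' @export
open_vertices <- function(s) sort(names(s$status)[s$status == "open"])

#' Defence strategies
#'
#' A strategy is a sequence of per-turn defence sets, indexed from turn 1.
#' Vertices within a turn are distinct and no vertex appears in more than one
#' turn.
#'
#' @param turns list of character vectors (possibly empty) of vertex labels.
#' @return an object of class `strategy`.
#' @examples
#' strategy(list(c("D", "H"), "B"))
#' @export
strategy <- function(turns = list()) {
  turns <- lapply(turns, as.character)
  all_v <- unlist(turns)
  if (anyDuplicated(all_v)) {
    stop(sprintf("vertex '%s' defended more than once", all_v[duplicated(all_v)][1]))
  }
  structure(list(turns = turns), class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat("<strategy>", if (length(x$turns) == 0) "(empty)" else "", "\n")
  for (i in seq_along(x$turns)) {
    cat(sprintf("  turn %d: {%s}\n", i, paste(x$turns[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Cost-Fire problem instances
#'
#' Bundles a rooted graph, a cost function, a per-turn budget \eqn{b} and a
#' target number of saved vertices \eqn{k}.
#'
#' @param graph a [rooted_graph].
#' @param cost_fn a [cost_function].
#' @param budget positive integer per-turn defence budget.
#' @param target integer \eqn{\ge 1}, the number of vertices to save.
#' @return an object of class `cost_fire_instance`.
#' @export
cost_fire_instance <- function(graph, cost_fn, budget, target = 1L) {
  stopifnot(inherits(graph, "rooted_graph"), inherits(cost_fn, "cost_function"))
  budget <- as.integer(budget)
  target <- as.integer(target)
  if (budget < 1) stop("budget must be >= 1")
  if (target < 1) stop("target must be >= 1")
  structure(
    list(graph = graph, cost_fn = cost_fn, budget = budget, target = target),
    class = "cost_fire_instance"
  )
}

#' @export
print.cost_fire_instance <- function(x, ...) {
  cat(sprintf(
    "<cost_fire_instance> %d vertices, root '%s', cost '%s', budget %d, target %d\n",
    n_vertices(x$graph), x$graph$root, x$cost_fn$family, x$budget, x$target
  ))
  invisible(x)
}

#' Initial game state
#'
#' Fire breaks out at the root: the root is burning, every other vertex open,
#' at time 0.
#'
#' @param g a [rooted_graph].
#' @return a [game_state] at time 0.
#' @export
initial_state <- function(g) {
  status <- stats::setNames(rep("open", n_vertices(g)), g$vertices)
  status[g$root] <- "burning"
  game_state(0L, status)
}

#' Fire spread step
#'
#' Every open vertex adjacent to a burning vertex becomes burning; all other
#' vertices are unchanged; time advances by one.
#'
#' @param g a [rooted_graph].
#' @param s a [game_state].
#' @return the [game_state] one time step later.
#' @export
spread <- function(g, s) {
  burning <- names(s$status)[s$status == "burning"]
  frontier <- unique(unlist(g$adj[burning], use.names = FALSE))
  ignite <- frontier[s$status[frontier] == "open"]
  status <- s$status
  status[ignite] <- "burning"
  game_state(s$time + 1L, status)
}

#' Containment test
#'
#' The fire is contained when no open vertex is adjacent to a burning vertex.
#'
#' @param g a [rooted_graph].
#' @param s a [game_state].
#' @return logical.
#' @export
is_contained <- function(g, s) {
  burning <- names(s$status)[s$status == "burning"]
  frontier <- unique(unlist(g$adj[burning], use.names = FALSE))
  !any(s$status[frontier] == "open")
}

#' Play one turn: validate defences, apply them, spread fire
#'
#' Costs are evaluated against `s`, the state carried over from the previous
#' turn (so all of a turn's costs are frozen before any of its defences are
#' placed).  Each defended vertex must be open in `s`, and the summed costs
#' must not exceed the budget.
#'
#' @param g a [rooted_graph].
#' @param s the [game_state] at time `turn - 1`.
#' @param defence character vector of vertices to defend this turn.
#' @param cost_fn a [cost_function].
#' @param budget per-turn budget.
#' @param turn positive integer turn number (`s$time + 1`).
#' @param on_violation `"error"` to stop on an invalid defence, `"flag"` to
#'   return the violations alongside the state.
#' @return for `on_violation = "error"`, the post-spread [game_state] at time
#'   `turn`; for `"flag"`, a list with `state`, `cost` (total spent) and
#'   `violations` (character vector, empty when valid).
#' @export
apply_turn <- function(g, s, defence, cost_fn, budget, turn,
                       on_violation = c("error", "flag")) {
  on_violation <- match.arg(on_violation)
  if (s$time != turn - 1L) {
    stop(sprintf("state is at time %d; expected %d for turn %d", s$time, turn - 1L, turn))
  }
  defence <- as.character(defence)
  violations <- character(0)
  if (anyDuplicated(defence)) {
    violations <- c(violations, sprintf("turn %d: duplicate defence", turn))
    defence <- unique(defence)
  }
  unknown <- setdiff(defence, g$vertices)
  if (length(unknown) > 0) {
    violations <- c(violations,
                    sprintf("turn %d: unknown vertex '%s'", turn, unknown))
    defence <- setdiff(defence, unknown)
  }
  not_open <- defence[s$status[defence] != "open"]
  if (length(not_open) > 0) {
    violations <- c(violations,
                    sprintf("turn %d: vertex '%s' is not open", turn, not_open))
  }
  total <- 0L
  ok <- setdiff(defence, not_open)
  if (length(ok) > 0) {
    total <- sum(eval_costs(cost_fn, ok, turn, s, g))
    if (total > budget) {
      violations <- c(violations,
                      sprintf("turn %d: total cost %d exceeds budget %d", turn, total, budget))
    }
  }
  if (length(violations) > 0 && on_violation == "error") stop(violations[1])
  status <- s$status
  status[ok] <- "defended"
  out <- spread(g, game_state(s$time, status))
  if (on_violation == "error") out else list(state = out, cost = total, violations = violations)
}

#' Play a full game
#'
#' Starts from [initial_state()], applies one turn per strategy entry (padding
#' with empty defence sets once the strategy is exhausted) until the fire is
#' contained.  Containment is guaranteed within `n` turns.  A strategy with
#' defences scheduled after containment yields an invalid trace (the extra
#' defences are flagged), as do budget or openness violations along the way.
#'
#' @param inst a [cost_fire_instance].
#' @param strat a [strategy] (or list of character vectors).
#' @return an object of class `trace`: list with `states` (game states from
#'   time 0 to containment), `defences` (the [strategy] actually applied),
#'   `contained_at` (time of containment), `saved` (character vector of
#'   non-burning vertices at containment), `valid` (logical) and `violations`.
#' @examples
#' g <- rooted_graph_from_edges(rbind(c("u", "v")), root = "u")
#' inst <- cost_fire_instance(g, uniform_cost(), budget = 1, target = 1)
#' play(inst, strategy(list("v")))
#' @export
play <- function(inst, strat) {
  if (!inherits(strat, "strategy")) strat <- strategy(strat)
  g <- inst$graph
  s <- initial_state(g)
  states <- list(s)
  applied <- list()
  violations <- character(0)
  turn <- 0L
  while (!is_contained(g, s)) {
    turn <- turn + 1L
    defence <- if (turn <= length(strat$turns)) strat$turns[[turn]] else character(0)
    step <- apply_turn(g, s, defence, inst$cost_fn, inst$budget, turn,
                       on_violation = "flag")
    violations <- c(violations, step$violations)
    s <- step$state
    states[[turn + 1L]] <- s
    applied[[turn]] <- defence
  }
  if (length(strat$turns) > turn) {
    extra <- unlist(strat$turns[(turn + 1L):length(strat$turns)])
    if (length(extra) > 0) {
      violations <- c(violations,
                      sprintf("defences {%s} scheduled after containment at time %d",
                              paste(extra, collapse = ", "), turn))
    }
  }
  saved <- sort(names(s$status)[s$status != "burning"])
  structure(
    list(
      states = states,
      defences = strategy(applied),
      contained_at = turn,
      saved = saved,
      valid = length(violations) == 0,
      violations = violations
    ),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf(
    "<trace> contained at t = %d, %d saved, %s\n",
    x$contained_at, length(x$saved),
    if (x$valid) "valid" else paste0("INVALID (", x$violations[1], ")")
  ))
  invisible(x)
}

#' Number of vertices saved by a trace
#'
#' Defended and still-open vertices at containment both count as saved.
#'
#' @param tr a [trace].
#' @return integer.
#' @export
count_saved <- function(tr) length(tr$saved)

#' Decide a Cost-Fire instance under a given strategy
#'
#' @param inst a [cost_fire_instance].
#' @param strat a [strategy].
#' @return `TRUE` iff the strategy is valid and saves at least the target
#'   number of vertices.
#' @export
decide <- function(inst, strat) {
  tr <- play(inst, strat)
  tr$valid && count_saved(tr) >= inst$target
}
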
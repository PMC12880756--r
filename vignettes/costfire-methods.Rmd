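---
title: "Cost-Fire: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-Fire: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costfire)
```

## The model

Cost-Fire is a deterministic, perfect-information, one-player game on a
rooted undirected simple graph $(G = (V, E), r)$. At time 0 the root burns
and everything else is open. Each turn $i \ge 1$:

1. the game state carried over from turn $i - 1$ is frozen and every open
   vertex is priced by the cost function $c(v, i, \mathcal{S})$;
2. the defender picks a set $\sigma_i$ of open vertices with
   $\sum_{d \in \sigma_i} c(d, i, \mathcal{S}) \le b$ and defends them;
3. fire spreads: every open vertex adjacent to a burning vertex ignites.

Burning and defended are absorbing states, so both sets grow monotonically
and the game contains within $n = |V|$ turns (each uncontained turn burns at
least one new vertex). At containment all unburned vertices are saved.

Two readings of the turn structure were possible and the package fixes one:
costs for the whole of turn $i$ are evaluated against the *pre-defence*
state of turn $i$ (the post-spread state of turn $i-1$). This matches the
worked two-turn game in the README — the defences placed in a turn appear in
the same snapshot as the vertices that ignite that turn — and matches the
"recalculate costs at the start of every turn" discipline used by all the
stochastic families. The alternative (pricing each defence against the
state including the defences already placed this turn) would make a turn's
total spend depend on the order of defences within the turn, which the
set-valued strategy notation cannot express.

Other contract decisions, all enforced by the engine:

* costs are integers $\ge 1$; a family returning anything else raises an
  error (`eval_costs()` validates every call);
* strategies shorter than the game are padded with empty defence sets;
  strategies with defences scheduled *after* containment make the trace
  invalid rather than being silently truncated, since the decision problem
  quantifies over the state at time $|\sigma|$;
* vertex labels are opaque strings, and lexicographic label order is the
  deterministic tie-break everywhere (heuristics, solvers, greedy scans).

## Cost families

| family | kind | definition |
|---|---|---|
| `uniform_cost()` | static | constant 1 (recovers b-Fire / Fire) |
| `random_preference(seed)` | static | one draw per vertex from $U\{1..5\}$ |
| `burning_neighbours(b)` | state-dependent | $\max(b - f_{v,t}, 1)$, $f_{v,t}$ = burning neighbours |
| `distance_from_fire()` | state-dependent | hops to nearest fire |
| `periodic_cost()` | temporal | 2 on even turns, 1 on odd |
| `binary_hesitation(seed)` | temporal (stochastic) | 2 w.p. 0.297, else 1, fresh per vertex-turn |
| `threat_stochastic(spread, seed)` | temporal + state | distance $\pm U\{-a..a\}$, $a = 3$ (high) or 1 (low), clamped at 1 |

The 0.297 hesitation probability is an empirical vaccine-hesitancy rate;
the binary family redraws per turn (hesitancy fluctuates), whereas the
uniform preference is drawn once per game (a fixed disposition). Distances
to an unreachable fire are capped at $n$, the graph order: the cap exceeds
any realisable distance, stays finite, and only matters on disconnected
graphs, where a fire-free component should be (and is) effectively
undefendable-last rather than an error.

**Keyed randomness.** Every stochastic family hashes `(seed, family tag,
vertex, turn)` into a fresh 31-bit seed and draws once from it, instead of
consuming a shared sequential stream. The draw at a given vertex-turn is
therefore independent of evaluation order, which is what makes two core
invariants hold simultaneously: (i) replaying a stored trace's defences
reproduces the trace bit-for-bit, even though validation evaluates costs in
a different order than the heuristic that produced them; (ii) heuristic
randomness and cost randomness never interleave. The empirical cost-2 rate
of `binary_hesitation()` over $10^5$ distinct vertex-turn pairs sits within
Monte-Carlo error of 0.297 (checked in the test suite at three standard
errors, $\approx 0.0043$).

## Heuristics

`select_defences()` ranks the open vertices by the primary criterion
(random shuffle / highest degree / least distance to fire / least cost),
breaks ties by an optional secondary criterion and then by label, and scans
greedily: every vertex whose turn-start cost fits the remaining budget is
taken. Unaffordable vertices are *skipped, not stopping the scan* — the
selection stops only when no remaining open vertex fits — so the returned
set always saturates the budget as far as the ordering allows. All open
vertices are eligible, not only threatened ones; threat-restricted play
emerges from the threat criterion itself. The random heuristic reshuffles
once per turn (keyed on seed and turn number), making whole games
reproducible from the spec's seed.

## Exact solvers and numerical choices

**`brute_force_optimal()`** is the oracle all other solvers are tested
against: exhaustive search over *all* affordable subsets of open vertices
per turn. Restricting to maximal subsets would be unsound — with
state-dependent costs, defending more now can raise prices later (fewer
burning neighbours, larger distances) — so non-maximal subsets are kept.
States are memoised on (burning set, defended set), with the turn number
added to the key only for time-dependent families; for static and purely
state-dependent costs the value of a position is time-invariant. The
default size cap is 12 vertices. An optional `prune_adjacent` switch
restricts candidates to fire-adjacent open vertices; this is lossless for
unit-cost budget-1 play on trees (an optimal strategy defends next to the
fire there) and is what makes the 25-vertex Sea Fan sweeps feasible, but it
is not valid in general and is off by default.

**`solve_complete()`** covers any graph whose root neighbours every vertex:
everything undefended in turn 1 burns in turn 1, so the optimum is the
single-turn greedy by ascending turn-1 cost (ties by label).

**`solve_pl_free()`** enumerates ordered sequences of distinct non-root
vertices up to length $b(\ell - 2)$ — on a graph with no induced path on
$\ell$ vertices the game lasts at most $\ell - 2$ turns — and simulates
each. The per-turn consumption rule for a sequence is: scan the remaining
entries in order; discard burning entries permanently; defend affordable
open entries; *retain* unaffordable entries for later turns. The proof
sketch behind the algorithm is ambiguous between skipping and halting at an
unaffordable entry; since every ordering is enumerated, any consistent rule
preserves optimality, and skipping weakly dominates halting. Outcomes are
validated by a depth-first search from the root over the graph minus the
defended set (at containment the burned set is exactly the root's component
there), which the tests cross-check against engine replays.

**Pathcontainable trees.** An instance on a tree is Pathcontainable when
(1) open vertices beside the fire never cost more than open vertices away
from it, and (2) for any burning vertex with $x$ open neighbours, any
$x - 1$ of them are affordable — equivalently, their total cost minus the
cheapest is within budget. Under these properties an optimal play burns
only a shortest path to the nearest *defensible* vertex (one whose open
neighbours are all affordable when fire reaches it).
`solve_pathcontainable_tree()` scans vertices in breadth-first (distance,
label) order and simulates the path strategy for each — defend all open
neighbours of the newest burning path vertex except the next path vertex,
and at the target all of them — returning the first candidate whose
simulation respects the budget. Defensibility is judged at the simulated
turn the fire arrives, not at time 0, because the properties are stated
over states and a static pre-check would be wrong for state-dependent
costs. The definition leaves open *which* states the properties quantify
over, so `check_pathcontainable()` offers three modes: `trace` (checked
along a concrete play; used automatically to flag the solver's result),
`exhaustive` (all connected root-containing burning sets, trees up to 12
vertices, defences empty and the turn taken as the earliest the set is
reachable — defended sets are not enumerated, which would cube the state
space), and `declared` (caller assertion, for instances known analytically
to qualify).

**Sea Fans.** An $(f, \ell)$-Sea Fan is a rooted tree of $f$ fronds, each a
path of $\ell$ vertices whose terminal carries two leaves, so
$|V| = f(\ell + 2) + 1$. "Path of length $\ell$" is read as $\ell$
*vertices*: that is the single geometry under which the closed form for the
classic-Fire optimum,
$$k_{\max} = \begin{cases} f(2\ell + 5 - f)/2 & f \le \ell\\ \ell(\ell+5)/2 + 1 & f > \ell,\end{cases}$$
and the reduction's distance arithmetic are simultaneously consistent; the
closed form is verified against the brute-force oracle for all
$1 \le f, \ell \le 4$ rather than trusted (its $f > \ell$ derivation elides
middle terms).

**SAT reduction.** `reduce_2n2p_to_costfire()` maps a 2N2P-SAT formula
($n$ variables, each twice positive and twice negative, $m = 4n/3$ clauses
of 3 literals) onto a $(2n, n + 2m)$-Sea Fan with budget 2 and target
$k = n + 3m$: fronds end in literal vertices, their leaves are labelled by
the clauses containing each occurrence, and the purely temporal cost
schedule makes exactly one variable's two phases affordable at each time
$t \le n$ (cost 2 each) and exactly one clause's leaves at each time
$n + j$ (cost 1 each), everything else costing 3 — including all times
beyond $n + m$, where the schedule is silent and the extension keeps late
defence unaffordable, as the correctness argument implicitly assumes.
Clauses containing the same literal twice label both of that literal
vertex's leaves. `decide_reduced_instance()` exploits the schedule: it
searches the $3^n$ per-variable phase choices, completes each with the
greedy clause phase, and replays every candidate through the engine, so
the reported maximum is an engine-verified count, and the decision is
exactly satisfiability. A structural note uncovered while building the
test battery: for $n = 3$ a *random* 2N2P formula is almost always
satisfiable (each 3-literal clause excludes at most two of the eight
assignments, and excluding all eight requires a deliberate tiling), so the
battery pairs random satisfiable formulas with a constructed unsatisfiable
one whose four clauses exclude all eight assignments.

## Generators and the experiment harness

`random_graph()` wraps the standard samplers (Erdős–Rényi, Barabási–Albert,
Watts–Strogatz, geometric, random regular) and adds two models written
in-package: the Holme–Kim clustered power-law graph (preferential
attachment with a probability-$p$ triangle-closing step) and the connected
caveman graph, where one edge of each clique is rewired to the next clique
so the rewired edges form a central cycle — the rewiring target is the
design choice that guarantees connectivity. The outbreak vertex is drawn
uniformly per trial.

`run_experiment()` follows the study design the package is built around:
each trial draws one graph (100-vertex graphs, 50 trials in the original
study; the defaults are free parameters of `experiment_config()`) and one
root, shared across every (budget, cost, heuristic) cell of that trial;
per-cell seeds are derived by hashing (master seed, trial, cell), so a
configuration is byte-reproducible and cells are statistically independent.
Summaries report the per-cell median with a bootstrap percentile 95%
confidence interval (1000 resamples); the interval construction is not
pinned down by the envelope the original plots draw, and the percentile
bootstrap was chosen as the assumption-free default for a median over 50
trials. No wall-clock timeout is reproduced: desk-scale runs finish in
seconds.

The test suite exercises the harness at reduced scale — 20-vertex graphs,
2–5 trials, oracle sweeps over all admissible instances with at most 9
vertices and Sea Fans to 25 — sizes chosen so the full suite runs in well
under a minute while still crossing every code path; the engine and solver
properties being checked (monotonicity, containment, budget compliance,
oracle agreement) are size-uniform, so small instances are the efficient
place to check them.

What the synthetic models do *not* emulate about real contact networks:
the assortativity and clustering profiles of real animal contact graphs
(none of the models is fitted to data), edge weights and temporal contact
patterns (ignored by the unweighted, static game), and multi-source
outbreaks. Passing tests therefore certify the game mechanics and solver
correctness, not epidemiological fidelity of any particular model fit.

## Limitations

* Graphs are undirected and unweighted; costs are integers (rationals would
  transfer up to a multiplicative factor but are not implemented).
* The brute-force oracle is exponential and capped at 12 vertices
  (25 with adjacency pruning on trees); the sequence-enumeration solver is
  practical only for small $b(\ell - 2)$.
* The treewidth-parameterised tractability route (logic-based dynamic
  programming) is out of scope; no optimality is claimed for the
  heuristics, which is precisely why the oracle exists.
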
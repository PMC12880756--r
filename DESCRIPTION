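Package: costfire
Title: The Firefighter Game with Dynamic Defence Costs on Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and exact solution of Cost-Fire, a discrete-time
    contagion-containment game on graphs in which a fire (infection) spreads
    from a root vertex and a defender spends a per-turn budget on defending
    vertices whose costs may depend on time and on the game state. Provides
    the turn-based game engine, a library of static, temporal and
    state-dependent cost functions, budgeted greedy defence heuristics,
    exact solvers for complete graphs, bounded-path-length graphs and
    Pathcontainable trees, a brute-force optimal-play oracle, Sea Fan and
    random-graph generators, a SAT-based hardness-reduction instance
    generator, and a seeded simulation-experiment harness with bootstrap
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
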
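test_that("uniform cost is the constant 1", {
  g <- worked_example_graph()
  cf <- uniform_cost()
  s <- initial_state(g)
  expect_equal(cf$kind, "static")
  expect_equal(eval_costs(cf, open_vertices(s), 1, s, g), rep(1L, 8))
  expect_equal(sum(eval_costs(cf, c("D", "H"), 1, s, g)), 2)
})

test_that("random preference draws each vertex once from {1..5}", {
  g <- gnm_graph(40, 80, 1)
  s <- initial_state(g)
  cf <- random_preference(11)
  costs <- eval_costs(cf, g$vertices, 1, s, g)
  expect_true(all(costs %in% 1:5))
  # static: independent of time and state
  s2 <- spread(g, s)
  expect_identical(eval_costs(cf, g$vertices, 5, s2, g), costs)
  # same seed, same map; different seed, (almost surely) different map
  expect_identical(eval_costs(random_preference(11), g$vertices, 1, s, g), costs)
  expect_false(identical(eval_costs(random_preference(12), g$vertices, 1, s, g), costs))
})

test_that("burning-neighbour counts discount the cost down to 1", {
  g <- worked_example_graph()
  cf <- burning_neighbours(4)
  s <- initial_state(g)
  expect_equal(cf$kind, "purely_state_dependent")
  # A has one burning neighbour (r): 4 - 1 = 3; E has none: 4
  expect_equal(eval_costs(cf, c("A", "E"), 1, s, g), c(3L, 4L))
  s1 <- spread(g, s)  # A, C, D, H burning too; B has 2 burning neighbours
  expect_equal(eval_costs(cf, "B", 2, s1, g), 2L)
  # clamp at 1 when burning neighbours reach the anchor
  cf2 <- burning_neighbours(1)
  expect_equal(eval_costs(cf2, c("A", "E"), 1, s, g), c(1L, 1L))
})

test_that("distance-from-fire costs are hop counts with cap n", {
  g <- worked_example_graph()
  cf <- distance_from_fire()
  s <- initial_state(g)
  expect_equal(eval_costs(cf, c("A", "B", "E", "G"), 1, s, g), c(1L, 2L, 3L, 5L))
  disc <- rooted_graph_from_edges(rbind(c("a", "b"), c("c", "d")), root = "a")
  sd <- initial_state(disc)
  expect_equal(eval_costs(cf, "c", 1, sd, disc), n_vertices(disc))
})

test_that("periodic cost doubles on even turns", {
  g <- path_graph(3)
  s <- initial_state(g)
  cf <- periodic_cost()
  expect_equal(cf$kind, "purely_temporal")
  expect_equal(eval_costs(cf, "p02", 0, s, g), 2L)
  expect_equal(eval_costs(cf, "p02", 3, s, g), 1L)
  expect_equal(eval_costs(cf, "p02", 4, s, g), 2L)
})

test_that("binary hesitation is a seeded 1-or-2 draw per vertex-turn", {
  g <- gnm_graph(25, 60, 2)
  s <- initial_state(g)
  cf <- binary_hesitation(3)
  draws <- unlist(lapply(1:40, function(t) eval_costs(cf, g$vertices, t, s, g)))
  expect_true(all(draws %in% 1:2))
  expect_gt(mean(draws == 2), 0.2)  # rough band; calibration tested at scale
  expect_lt(mean(draws == 2), 0.4)
  expect_identical(eval_costs(binary_hesitation(3), g$vertices, 7, s, g),
                   eval_costs(cf, g$vertices, 7, s, g))
})

test_that("stochastic threat stays within its noise band and above 0", {
  g <- worked_example_graph()
  s <- initial_state(g)
  d <- eval_costs(distance_from_fire(), open_vertices(s), 1, s, g)
  for (seed in 1:5) {
    lo <- eval_costs(threat_stochastic("low", seed), open_vertices(s), 1, s, g)
    expect_true(all(lo >= pmax(1, d - 1) & lo <= d + 1))
    hi <- eval_costs(threat_stochastic("high", seed), open_vertices(s), 1, s, g)
    expect_true(all(hi >= pmax(1, d - 3) & hi <= d + 3))
  }
})

test_that("every family returns integers >= 1 on random reachable states", {
  fams <- function(seed) list(
    uniform_cost(), random_preference(seed), burning_neighbours(3),
    distance_from_fire(), periodic_cost(), binary_hesitation(seed),
    threat_stochastic("high", seed)
  )
  for (seed in 1:3) {
    g <- random_connected_graph(12, seed)
    tr <- play_heuristic(cost_fire_instance(g, uniform_cost(), 2),
                         heuristic_spec("random", seed = seed))
    for (s in tr$states) {
      open <- open_vertices(s)
      if (length(open) == 0) next
      for (cf in fams(seed)) {
        costs <- eval_costs(cf, open, s$time + 1, s, g)
        expect_true(all(costs >= 1 & costs == round(costs)))
      }
    }
  }
})

test_that("kind classification matches actual dependence", {
  g <- random_connected_graph(10, 4)
  s0 <- initial_state(g)
  s1 <- spread(g, s0)
  open <- open_vertices(s1)
  for (cf in list(uniform_cost(), random_preference(5), distance_from_fire(),
                  burning_neighbours(2))) {
    # static and purely state-dependent: time does not matter
    expect_identical(eval_costs(cf, open, 1, s1, g), eval_costs(cf, open, 9, s1, g))
  }
  s1b <- s1; s1b$time <- s0$time  # same assignment viewed at matching times
  for (cf in list(uniform_cost(), random_preference(5), periodic_cost(),
                  binary_hesitation(6))) {
    # static and purely temporal: state does not matter
    expect_identical(eval_costs(cf, open, 3, s0, g), eval_costs(cf, open, 3, s1, g))
  }
  expect_error(
    eval_costs(cost_function("bad", "static", function(v, t, s, g) rep(0L, length(v))),
               open, 1, s1, g),
    "integer >= 1"
  )
})
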
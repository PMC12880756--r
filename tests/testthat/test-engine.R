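test_that("the initial state burns only the root", {
  g <- worked_example_graph()
  s <- initial_state(g)
  expect_equal(s$time, 0L)
  expect_equal(burning_vertices(s), "r")
  expect_equal(open_vertices(s), LETTERS[1:8])

  g1 <- rooted_graph_from_edges(matrix(character(0), ncol = 2), root = "a",
                                isolated = "a")
  s1 <- initial_state(g1)
  expect_equal(burning_vertices(s1), "a")
  expect_length(open_vertices(s1), 0)
})

test_that("spread ignites exactly the open neighbours of fire", {
  st <- star_graph(4)
  s1 <- spread(st, initial_state(st))
  expect_equal(burning_vertices(s1), sort(c("c", sprintf("l%02d", 1:4))))

  # all fire-adjacent vertices defended: spread is a fixed point on burning
  g <- worked_example_graph()
  status <- stats::setNames(rep("open", 9), g$vertices)
  status["r"] <- "burning"
  status[c("A", "C", "D", "H")] <- "defended"
  s <- game_state(1, status)
  expect_true(is_contained(g, s))
  expect_equal(burning_vertices(spread(g, s)), "r")
})

test_that("the worked two-turn game reproduces its printed states", {
  g <- worked_example_graph()
  cf <- uniform_cost()
  s0 <- initial_state(g)
  s1 <- apply_turn(g, s0, c("D", "H"), cf, budget = 2, turn = 1)
  expect_equal(burning_vertices(s1), c("A", "C", "r"))
  expect_equal(defended_vertices(s1), c("D", "H"))
  expect_false(is_contained(g, s1))
  s2 <- apply_turn(g, s1, "B", cf, budget = 2, turn = 2)
  expect_equal(burning_vertices(s2), c("A", "C", "r"))
  expect_equal(defended_vertices(s2), c("B", "D", "H"))
  expect_true(is_contained(g, s2))
  expect_equal(sum(s2$status != "burning"), 6)
})

test_that("apply_turn rejects bad defences and blown budgets", {
  g <- worked_example_graph()
  cf <- uniform_cost()
  s0 <- initial_state(g)
  expect_error(apply_turn(g, s0, "r", cf, 2, 1), "'r' is not open")
  expect_error(apply_turn(g, s0, c("A", "B", "C"), cf, 2, 1), "exceeds budget")
  flagged <- apply_turn(g, s0, "r", cf, 2, 1, on_violation = "flag")
  expect_match(flagged$violations, "turn 1.*'r'")
  # empty defence with tiny budget is a pure spread step
  s1 <- apply_turn(g, s0, character(0), cf, 1, 1)
  expect_equal(burning_vertices(s1), sort(c("r", "A", "C", "D", "H")))
})

test_that("play pads short strategies and flags over-long ones", {
  g2 <- rooted_graph_from_edges(rbind(c("u", "v")), root = "u")
  inst <- cost_fire_instance(g2, uniform_cost(), 1, 1)
  tr <- play(inst, strategy(list("v")))
  expect_true(tr$valid)
  expect_equal(tr$states[[2]]$status, c(u = "burning", v = "defended"))
  expect_equal(tr$saved, "v")
  expect_true(decide(inst, strategy(list("v"))))

  g <- worked_example_graph()
  inst2 <- cost_fire_instance(g, uniform_cost(), 1, 1)
  tr2 <- play(inst2, strategy())
  expect_true(tr2$valid)
  expect_equal(count_saved(tr2), 0)
  expect_lte(tr2$contained_at, n_vertices(g))

  # defences scheduled after containment invalidate the trace
  inst3 <- cost_fire_instance(g, uniform_cost(), 2, 1)
  tr3 <- play(inst3, strategy(list(c("D", "H"), "B", "E")))
  expect_false(tr3$valid)
  expect_match(tr3$violations, "after containment")
})

test_that("saved counts include both defended and sheltered vertices", {
  g <- worked_example_graph()
  inst <- cost_fire_instance(g, uniform_cost(), 2, 6)
  tr <- play(inst, strategy(list(c("D", "H"), "B")))
  expect_equal(tr$contained_at, 2)
  expect_equal(count_saved(tr), 6)
  expect_setequal(tr$saved, c("B", "D", "H", "E", "F", "G"))
  expect_true(decide(inst, strategy(list(c("D", "H"), "B"))))
  inst7 <- cost_fire_instance(g, uniform_cost(), 2, 7)
  expect_false(decide(inst7, strategy(list(c("D", "H"), "B"))))

  g1 <- rooted_graph_from_edges(matrix(character(0), ncol = 2), root = "a",
                                isolated = "a")
  tr1 <- play(cost_fire_instance(g1, uniform_cost(), 1, 1), strategy())
  expect_equal(count_saved(tr1), 0)
})

test_that("burning and defended sets grow monotonically and stay disjoint", {
  for (seed in 1:5) {
    g <- random_connected_graph(14, seed)
    inst <- cost_fire_instance(g, binary_hesitation(seed), budget = 2)
    spec <- heuristic_spec("random", seed = seed)
    tr <- play_heuristic(inst, spec)
    expect_true(tr$valid)
    expect_lte(tr$contained_at, n_vertices(g))
    prev_b <- character(0); prev_d <- character(0)
    for (s in tr$states) {
      b <- burning_vertices(s); d <- defended_vertices(s)
      expect_true(all(prev_b %in% b))
      expect_true(all(prev_d %in% d))
      expect_length(intersect(b, d), 0)
      prev_b <- b; prev_d <- d
    }
    expect_true(all(turn_costs(inst, tr) <= inst$budget))
  }
})

test_that("replaying a trace's defences reproduces it exactly", {
  for (seed in 6:8) {
    g <- random_connected_graph(12, seed)
    inst <- cost_fire_instance(g, threat_stochastic("low", seed), budget = 3)
    tr <- play_heuristic(inst, heuristic_spec("threat", tiebreak = "cost"))
    tr2 <- play(inst, tr$defences)
    expect_identical(tr2$states, tr$states)
    expect_identical(tr2$saved, tr$saved)
  }
})

test_that("uniform costs with budget b recover budgeted classic play", {
  # with budget 1 and unit costs, exactly one defence fits per turn
  g <- path_graph(6)
  inst <- cost_fire_instance(g, uniform_cost(), 1, 1)
  tr <- play(inst, strategy(list("p02")))
  expect_equal(count_saved(tr), 5)
  expect_error(
    apply_turn(g, initial_state(g), c("p02", "p03"), uniform_cost(), 1, 1),
    "exceeds budget"
  )
})
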
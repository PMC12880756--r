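test_that("the brute-force oracle handles the textbook miniatures", {
  tri <- rooted_graph_from_edges(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                                 root = "a")
  res <- brute_force_optimal(cost_fire_instance(tri, uniform_cost(), 1, 1))
  expect_equal(res$max_saved, 1)
  expect_equal(count_saved(play(cost_fire_instance(tri, uniform_cost(), 1, 1),
                                res$strategy)), 1)

  p2 <- rooted_graph_from_edges(rbind(c("u", "v")), root = "u")
  expect_equal(brute_force_optimal(cost_fire_instance(p2, uniform_cost(), 1, 1))$max_saved, 1)

  big <- gnm_graph(14, 25, 1)
  expect_error(brute_force_optimal(cost_fire_instance(big, uniform_cost(), 1, 1)),
               "size cap")
})

test_that("optimal saved counts never drop when the budget grows", {
  for (seed in 1:3) {
    g <- random_connected_graph(8, seed)
    for (cf in list(uniform_cost(), random_preference(seed), distance_from_fire())) {
      saved <- vapply(1:3, function(b) {
        brute_force_optimal(cost_fire_instance(g, cf, b, 1))$max_saved
      }, 1L)
      expect_true(all(diff(saved) >= 0))
    }
  }
})

test_that("witness strategies replay to exactly the reported optimum", {
  for (seed in 4:6) {
    g <- random_tree(8, seed)
    inst <- cost_fire_instance(g, burning_neighbours(3), 2, 1)
    res <- brute_force_optimal(inst)
    tr <- play(inst, res$strategy)
    expect_true(tr$valid)
    expect_equal(count_saved(tr), res$max_saved)
  }
})

test_that("root-adjacent-to-all instances reduce to a one-turn greedy", {
  k4 <- complete_graph(4)
  expect_equal(solve_complete(cost_fire_instance(k4, uniform_cost(), 2, 1))$max_saved, 2)

  cf <- cost_function("fixed", "static", function(v, t, s, g) {
    c(k02 = 1L, k03 = 2L, k04 = 3L)[v]
  })
  inst <- cost_fire_instance(k4, cf, 3, 1)
  expect_equal(solve_complete(inst)$max_saved, 2)
  expect_equal(brute_force_optimal(inst)$max_saved, 2)
  # budget below the cheapest vertex: nothing can be defended
  expect_equal(solve_complete(cost_fire_instance(k4, cf, 1, 1))$max_saved, 1)
  inst0 <- cost_fire_instance(k4, cost_function("fixed", "static",
    function(v, t, s, g) rep(5L, length(v))), 4, 1)
  expect_equal(solve_complete(inst0)$max_saved, 0)

  p3 <- path_graph(3)
  expect_error(solve_complete(cost_fire_instance(p3, uniform_cost(), 1, 1)),
               "not adjacent")
  # stars rooted at the centre qualify
  st <- star_graph(5)
  expect_equal(solve_complete(cost_fire_instance(st, uniform_cost(), 3, 1))$max_saved, 3)
})

test_that("complete-graph greedy matches the oracle across costs and budgets", {
  for (n in 4:6) {
    g <- complete_graph(n)
    for (seed in 1:2) for (b in 1:3) {
      for (cf in list(random_preference(seed), uniform_cost())) {
        inst <- cost_fire_instance(g, cf, b, 1)
        expect_equal(solve_complete(inst)$max_saved,
                     brute_force_optimal(inst)$max_saved)
      }
    }
  }
})

test_that("the Sea Fan closed form matches its arithmetic anchors", {
  expect_equal(sea_fan_fire_max_saved(1, 1), 3)
  expect_equal(sea_fan_fire_max_saved(2, 2), 7)
  expect_equal(sea_fan_fire_max_saved(3, 2), 8)
  expect_error(sea_fan_fire_max_saved(0, 2), ">= 1")
  # oracle agreement on a couple of small fans (full sweep in acceptance)
  for (par in list(c(2, 2), c(3, 2))) {
    sf <- make_sea_fan(par[1], par[2])
    inst <- cost_fire_instance(sf, uniform_cost(), 1, 1)
    expect_equal(brute_force_optimal(inst, size_cap = 15)$max_saved,
                 sea_fan_fire_max_saved(par[1], par[2]))
  }
})

test_that("sequence enumeration solves bounded-path-length instances", {
  # edgeless graph: nothing spreads, everything but the root is saved
  iso <- rooted_graph_from_edges(matrix(character(0), ncol = 2), root = "a",
                                 isolated = c("a", "b", "c", "d"))
  expect_equal(solve_pl_free(cost_fire_instance(iso, uniform_cost(), 1, 1), 2)$max_saved, 3)

  # cographs are P4-free: oracle equivalence on random cographs
  for (seed in 1:4) {
    g <- random_cograph(6, seed)
    for (cf in list(uniform_cost(), random_preference(seed))) {
      inst <- cost_fire_instance(g, cf, 2, 1)
      expect_equal(solve_pl_free(inst, 4)$max_saved,
                   brute_force_optimal(inst)$max_saved)
    }
  }

  # complete graphs are P3-free: agreement with the dedicated solver
  k4 <- complete_graph(4)
  for (b in 1:3) {
    inst <- cost_fire_instance(k4, uniform_cost(), b, 1)
    expect_equal(solve_pl_free(inst, 3)$max_saved, solve_complete(inst)$max_saved)
  }
  expect_error(solve_pl_free(cost_fire_instance(k4, uniform_cost(), 1, 1), 1), "l >= 2")
})

test_that("Pathcontainable checks hold and fail where the theory says", {
  tree <- random_tree(8, 1)
  maxdeg <- max(igraph::degree(tree$graph))
  inst <- cost_fire_instance(tree, uniform_cost(), max(maxdeg - 1, 1), 1)
  rep1 <- check_pathcontainable(inst, mode = "exhaustive")
  expect_equal(rep1$property1$status, "holds")
  expect_equal(rep1$property2$status, "holds")

  # unit costs, root of degree b + 2: all-but-two root neighbours affordable,
  # so property 2 fails at the root
  st <- star_graph(4)  # degree 4 root, budget 2
  inst2 <- cost_fire_instance(st, uniform_cost(), 2, 1)
  rep2 <- check_pathcontainable(inst2, mode = "exhaustive")
  expect_equal(rep2$property2$status, "fails")
  expect_match(rep2$property2$witness, "'c'")

  # burning-neighbour costs with ample budget hold along sampled traces
  for (seed in 2:4) {
    tr <- random_tree(9, seed, max_children = 2)
    inst3 <- cost_fire_instance(tr, burning_neighbours(2), 4, 1)
    trace <- play_heuristic(inst3, heuristic_spec("threat", tiebreak = "cost"))
    rep3 <- check_pathcontainable(inst3, mode = "trace", trace = trace)
    expect_equal(rep3$property2$status, "holds")
  }

  expect_equal(check_pathcontainable(inst, mode = "declared")$property1$status,
               "declared")
})

test_that("the path strategy solves Pathcontainable trees optimally", {
  p5 <- path_graph(5)
  res <- solve_pathcontainable_tree(cost_fire_instance(p5, uniform_cost(), 1, 1))
  expect_equal(res$max_saved, 4)   # the root itself is defensible
  expect_false(res$flagged)

  st <- star_graph(5)
  inst <- cost_fire_instance(st, uniform_cost(), 4, 1)
  expect_equal(solve_pathcontainable_tree(inst)$max_saved, 4)
  expect_equal(brute_force_optimal(inst)$max_saved, 4)

  # exhaustive oracle sweep: trees with at most 2 children, unit costs, b = 1
  for (seed in 1:6) {
    g <- random_tree(4 + seed, seed, max_children = 2)
    inst <- cost_fire_instance(g, uniform_cost(), 1, 1)
    res <- solve_pathcontainable_tree(inst)
    expect_equal(res$max_saved, brute_force_optimal(inst)$max_saved)
    expect_false(res$flagged)
  }
  # and with larger budgets on max-(b+1)-children trees
  for (b in 2:3) for (seed in 7:8) {
    g <- random_tree(8, seed, max_children = b)
    inst <- cost_fire_instance(g, uniform_cost(), b, 1)
    expect_equal(solve_pathcontainable_tree(inst)$max_saved,
                 brute_force_optimal(inst)$max_saved)
  }
  expect_error(
    solve_pathcontainable_tree(cost_fire_instance(complete_graph(3), uniform_cost(), 1, 1)),
    "not on a tree"
  )
})

test_that("reduction decisions mirror satisfiability with honest witnesses", {
  sat_phis <- lapply(1:3, function(s) random_2n2p_sat(3, seed = s))
  for (phi in c(sat_phis, list(unsat_2n2p_n3()))) {
    truth <- sat_satisfiable(phi)
    dec <- decide_reduced_instance(phi)
    expect_equal(dec$decision, truth)
    # witness replays through the engine within budget every turn
    tr <- play(dec$instance, dec$result$strategy)
    expect_true(tr$valid)
    expect_equal(count_saved(tr), dec$result$max_saved)
    expect_true(all(turn_costs(dec$instance, tr) <= dec$instance$budget))
    if (truth) expect_gte(count_saved(tr), dec$instance$target)
  }
})
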
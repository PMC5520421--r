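test_that("reachable graph is the closure of the initial state", {
  fx <- an_builtin("fig1")
  g <- reachable_graph(fx$net, fx$initial)
  expect_true("a=0,b=1,c=0" %in% g$keys)  # one-step successor via t4
  expect_equal(g$keys[1], "a=0,b=0,c=0")

  # every edge is a genuine single-step transition and the graph is closed
  for (r in seq_len(nrow(g$edges))) {
    s <- g$states[[g$edges$from[r]]]
    expect_equal(
      format_an_state(apply_transition(fx$net, s, g$edges$transition[r])),
      g$keys[g$edges$to[r]]
    )
  }

  # network with no transitions: a single state, no edges
  net0 <- parse_an(c('automaton "x" [0, 1]', 'initial "x"=0'))
  g0 <- reachable_graph(net0)
  expect_length(g0$states, 1)
  expect_equal(nrow(g0$edges), 0)

  # state count agrees with the independent depth-first enumeration
  for (seed in c(0, 9, 33, 120, 171)) {
    net <- corpus_net(seed)
    expect_length(reachable_graph(net)$states,
                  length(oracle_enumerate(net, net$initial)$states))
  }
})

test_that("the state cap aborts enumeration with a typed error", {
  fx <- an_builtin("fig1")
  expect_error(reachable_graph(fx$net, fx$initial, state_cap = 5),
               class = "an_state_cap")
})

test_that("attractors are the terminal strongly connected components", {
  fx <- an_builtin("fig1")
  att <- attractors(reachable_graph(fx$net, fx$initial))
  # one attractor contains no state with a=2
  expect_true(any(vapply(att$states, function(ss) {
    !any(grepl("a=2", ss, fixed = TRUE))
  }, logical(1))))

  # single state, no transitions
  net0 <- parse_an(c('automaton "x" [0, 1]', 'initial "x"=1'))
  att0 <- attractors(reachable_graph(net0))
  expect_equal(att0$states[[1]], "x=1")

  # an exitless cycle is the unique attractor
  tg <- toggle_net()
  gt <- reachable_graph(tg)
  att_t <- attractors(gt)
  expect_equal(nrow(att_t), 1)
  expect_equal(att_t$size, 4L)

  # agreement with the mutual-reachability oracle on random fixtures
  for (seed in c(2, 18, 44, 90, 133)) {
    net <- corpus_net(seed)
    att_pkg <- attractors(reachable_graph(net))
    att_or <- oracle_attractors(net, net$initial)
    expect_equal(att_pkg$states, att_or[order(vapply(att_or, `[`, "",  1),
                                              method = "radix")])
  }
})

test_that("goal-connected states form a backward-closed set", {
  fx <- an_builtin("fig1")
  g <- reachable_graph(fx$net, fx$initial)
  gc <- goal_connected(g, fx$goal)

  expect_true("a=0,b=0,c=0" %in% gc$state)  # s0 can still reach the goal
  # no state of the goal-free attractor is goal-connected
  att <- attractors(g)
  free <- att$states[[which(vapply(att$states, function(ss)
    !any(grepl("a=2", ss, fixed = TRUE)), logical(1)))[1]]]
  expect_length(intersect(free, gc$state), 0)

  # goal in the root: reflexivity of reachability
  g2 <- reachable_graph(fx$net, "a=2,b=0,c=0")
  expect_true("a=2,b=0,c=0" %in% goal_connected(g2, fx$goal)$state)

  # goal nowhere reachable: empty set
  net0 <- parse_an(c('automaton "x" [0, 1]', 'automaton "y" [0, 1]',
                     '"x" 0 -> 1 when "y"=1', 'initial "x"=0, "y"=0'))
  expect_equal(nrow(goal_connected(reachable_graph(net0), an_goal("x", 1))), 0)

  # invariant: no edge enters the goal-connected set from outside it
  for (seed in c(1, 27, 63, 150)) {
    net <- corpus_net(seed)
    gr <- reachable_graph(net)
    for (goal in corpus_goals(net)) {
      conn <- gr$keys %in% goal_connected(gr, goal)$state
      expect_false(any(!conn[gr$edges$from] & conn[gr$edges$to]))
    }
  }
})

test_that("exact bifurcations are the crossing edges of the goal boundary", {
  fx <- an_builtin("fig1")
  eb <- exact_bifurcations(fx$net, fx$initial, fx$goal)
  expect_equal(eb$transition, "t8")
  # witnesses satisfy s_u = s_b . t_b
  w <- eb$witnesses[[1]]
  for (r in seq_len(nrow(w))) {
    s_b <- an_state(fx$net, w$s_b[r])
    expect_equal(format_an_state(apply_transition(fx$net, s_b, "t8")),
                 w$s_u[r])
  }

  # goal b=1 is reachable from everywhere (t4 is unconditioned): no bifurcation
  expect_equal(nrow(exact_bifurcations(fx$net, fx$initial, an_goal("b", 1))), 0)

  # unreachable goal: no bifurcation by definition
  net0 <- parse_an(c('automaton "x" [0, 1]', 'automaton "y" [0, 1]',
                     '"x" 0 -> 1 when "y"=1', 'initial "x"=0, "y"=0'))
  expect_equal(nrow(exact_bifurcations(net0, net0$initial, an_goal("x", 1))), 0)

  # agreement with the direct CTL-characterization oracle
  for (seed in c(4, 21, 58, 96, 142)) {
    net <- corpus_net(seed)
    for (goal in corpus_goals(net)) {
      expect_setequal(
        exact_bifurcations(net, net$initial, goal)$transition,
        oracle_ctl_bifurcations(net, net$initial, goal)
      )
    }
  }
})

test_that("state graph exports round-trip and plot", {
  fx <- an_builtin("fig1")
  g <- reachable_graph(fx$net, fx$initial)

  js <- jsonlite::fromJSON(state_graph_json(g))
  expect_equal(js$root, "a=0,b=0,c=0")
  expect_length(js$states, length(g$states))
  expect_equal(nrow(js$edges), nrow(g$edges))

  dot <- state_graph_dot(g)
  expect_match(dot, "digraph", fixed = TRUE)
  expect_match(dot, "t8", fixed = TRUE)

  td <- tidy(g)
  expect_equal(nrow(td), nrow(g$edges))
  gl <- glance(g)
  expect_equal(gl$n_states, length(g$states))

  p <- autoplot(g, goal = fx$goal)
  expect_s3_class(p, "ggplot")
})
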
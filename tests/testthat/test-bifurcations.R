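test_that("the approximate search uncovers the worked-example bifurcation", {
  fx <- an_builtin("fig1")
  b3 <- find_bifurcations(fx$net, fx$initial, fx$goal, mode = "I3")
  expect_true("t8" %in% b3$transition)
  expect_equal(b3$method, rep("I3", nrow(b3)))

  b3s <- find_bifurcations(fx$net, fx$initial, fx$goal, mode = "I3sharp")
  exact <- exact_bifurcations(fx$net, fx$initial, fx$goal)$transition
  expect_true(all(b3$transition %in% exact))
  expect_true(all(b3s$transition %in% exact))

  # witnesses are consistent: s_u = s_b . t_b, refuted from s_u
  td <- tidy(b3)
  for (r in seq_len(nrow(td))) {
    s_b <- an_state(fx$net, td$s_b[r])
    s_u <- apply_transition(fx$net, s_b, td$transition[r])
    expect_equal(format_an_state(s_u), td$s_u[r])
    expect_false(oa_reach(fx$net, s_u, fx$goal)$decision)
  }
})

test_that("an empty goal encoding yields no bifurcations", {
  fx <- an_builtin("fig1")
  enc <- encode_goal_states(fx$net, list())
  s0 <- c(fx$initial, "_goal" = 0L)
  expect_equal(nrow(find_bifurcations(enc$net, s0, enc$goal, mode = "I3")), 0)
  expect_equal(nrow(find_bifurcations(enc$net, s0, enc$goal,
                                      mode = "I3sharp")), 0)
})

test_that("approximate results are sound on random fixtures", {
  for (seed in seq(0, 199, by = 10)) {
    net <- corpus_net(seed)
    for (goal in corpus_goals(net)) {
      exact <- exact_bifurcations(net, net$initial, goal)$transition
      for (mode in c("I3", "I3sharp")) {
        res <- find_bifurcations(net, net$initial, goal, mode = mode)
        expect_true(all(res$transition %in% exact),
                    info = paste("seed", seed, mode))
        # every reported witness is a genuine bifurcation occurrence
        td <- tidy(res)
        for (r in seq_len(nrow(td))) {
          s_b <- an_state(net, td$s_b[r])
          s_u <- an_state(net, td$s_u[r])
          expect_equal(apply_transition(net, s_b, td$transition[r]), s_u)
          expect_false(oa_reach(net, s_u, goal)$decision)
          expect_true(oracle_reach(net, s_b, goal))
          g <- reachable_graph(net)
          expect_true(format_an_state(s_b) %in% g$keys)
        }
      }
    }
  }
})

test_that("mode comparison reports consistent per-method sets", {
  fx <- an_builtin("fig1")
  rep1 <- classify_modes(fx$net, fx$initial, fx$goal)
  expect_equal(rep1$transitions[[which(rep1$method == "exact")]], "t8")
  for (m in c("I3", "I3sharp")) {
    expect_true(all(rep1$transitions[[which(rep1$method == m)]] %in% "t8"))
  }
  expect_true(all(rep1$seconds >= 0))

  # unreachable goal: every method agrees on the empty set
  net0 <- parse_an(c('automaton "x" [0, 1]', 'automaton "y" [0, 1]',
                     '"x" 0 -> 1 when "y"=1', 'initial "x"=0, "y"=0'))
  rep0 <- classify_modes(net0, net0$initial, an_goal("x", 1))
  expect_true(all(rep0$n == 0))

  # counts match a recomputation of the individual methods
  net <- corpus_net(17)
  goal <- corpus_goals(net)[[1]]
  rep2 <- classify_modes(net, net$initial, goal)
  expect_equal(rep2$n[rep2$method == "exact"],
               nrow(exact_bifurcations(net, net$initial, goal)))
  expect_equal(rep2$n[rep2$method == "I3"],
               nrow(find_bifurcations(net, net$initial, goal, mode = "I3")))
})

test_that("result exports are machine-readable", {
  fx <- an_builtin("fig1")
  res <- find_bifurcations(fx$net, fx$initial, fx$goal, mode = "I3",
                           all_witnesses = TRUE)
  js <- jsonlite::fromJSON(bifurcations_json(res), simplifyVector = FALSE)
  expect_equal(js[[1]]$transition, "t8")
  expect_equal(js[[1]]$automaton, "c")
  expect_equal(js[[1]]$condition$b, 0)
  tsv <- bifurcations_tsv(res)
  expect_equal(tsv$transition, "t8")
  expect_true(tsv$n_witnesses >= 1)
  gl <- glance(res)
  expect_equal(gl$n_transitions, 1L)
})
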
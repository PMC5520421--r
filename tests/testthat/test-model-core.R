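test_that("the worked-example network parses with 3 automata and 8 transitions", {
  fx <- an_builtin("fig1")
  expect_length(fx$net$automata, 3)
  expect_equal(nrow(fx$net$transitions), 8)
  expect_equal(fx$net$transitions$id, paste0("t", 1:8))
  # spot-check a conditioned transition: t3 = a 0 -> 2 when b=0, c=0
  t3 <- fx$net$transitions[3, ]
  expect_equal(t3$automaton, "a")
  expect_equal(c(t3$origin, t3$dest), c(0L, 2L))
  expect_equal(t3$condition[[1]], c(b = 0L, c = 0L))
})

test_that("parser accepts automata without transitions and flags bad input", {
  net <- parse_an(c('automaton "x" [0, 1]'))
  expect_equal(nrow(net$transitions), 0)

  # origin = dest violates the transition definition
  expect_error(
    parse_an(c('automaton "a" [0, 1]', '"a" 0 -> 0')),
    class = "an_semantic_error"
  )
  # undeclared local state
  expect_error(
    parse_an(c('automaton "a" [0, 1]', '"a" 0 -> 5')),
    class = "an_semantic_error"
  )
  # condition on the transition's own automaton
  expect_error(
    parse_an(c('automaton "a" [0, 1]', 'automaton "b" [0, 1]',
               '"a" 0 -> 1 when "a"=0')),
    class = "an_semantic_error"
  )
  # duplicate automaton, with the line number in the message
  expect_error(
    parse_an(c('automaton "a" [0, 1]', 'automaton "a" [0, 1]')),
    "line 2", class = "an_parse_error"
  )
  # plain syntax error
  expect_error(parse_an("automaton oops"), "line 1",
               class = "an_parse_error")
})

test_that("serialization round-trips to an identical network", {
  nets <- c(list(an_builtin("fig1")$net),
            lapply(c(0, 7, 23, 55, 101), corpus_net))
  for (net in nets) {
    txt <- serialize_an(net)
    net2 <- parse_an(txt)
    expect_identical(serialize_an(net2), txt)
    expect_identical(net2$automata, net$automata)
    expect_identical(net2$transitions$condition, net$transitions$condition)
  }
})

test_that("enabled returns exactly the applicable transitions", {
  fx <- an_builtin("fig1")
  expect_setequal(enabled(fx$net, fx$initial)$id, c("t2", "t3", "t4"))
  expect_equal(enabled(fx$net, "a=2,b=0,c=0")$id, "t4")

  # no origin matches anywhere
  net <- parse_an(c('automaton "x" [0, 1]', 'automaton "y" [0, 1]',
                    '"x" 0 -> 1 when "y"=1'))
  expect_equal(nrow(enabled(net, c(x = 1L, y = 0L))), 0)

  # agreement with the independent applicability oracle across the corpus
  for (seed in c(3, 14, 41, 77)) {
    rnet <- corpus_net(seed)
    s <- rnet$initial
    expect_setequal(enabled(rnet, s)$id,
                    rnet$transitions$id[oracle_enabled_rows(rnet, s)])
  }
})

test_that("apply_transition replaces exactly one coordinate", {
  fx <- an_builtin("fig1")
  expect_equal(apply_transition(fx$net, fx$initial, "t4"),
               an_state(fx$net, "a=0,b=1,c=0"))
  # unconditioned transition still only moves its own automaton
  expect_equal(apply_transition(fx$net, "a=1,b=0,c=0", "t1"),
               an_state(fx$net, "a=0,b=0,c=0"))
  expect_error(apply_transition(fx$net, "a=2,b=0,c=0", "t1"),
               class = "an_not_applicable")

  for (seed in c(5, 19, 60)) {
    net <- corpus_net(seed)
    s <- net$initial
    for (tid in enabled(net, s)$id) {
      s2 <- apply_transition(net, s, tid)
      a <- net$transitions$automaton[net$transitions$id == tid]
      expect_equal(sum(s2 != s), 1L)
      expect_true(names(which(s2 != s)) == a)
    }
  }
})

test_that("goal-state encoding adds a fresh conditioned goal automaton", {
  fx <- an_builtin("fig1")
  enc <- encode_goal_states(fx$net, list(c(a = 2L, b = 0L)))
  expect_true("_goal" %in% names(enc$net$automata))
  added <- enc$net$transitions[enc$net$transitions$automaton == "_goal", ]
  expect_equal(nrow(added), 1)
  expect_equal(added$condition[[1]], c(a = 2L, b = 0L))
  expect_equal(enc$goal$automaton, "_goal")
  expect_equal(enc$goal$index, 1L)

  # two target assignments give two conditioned transitions
  enc2 <- encode_goal_states(fx$net, list("a=2,b=0", "a=2,c=1"))
  expect_equal(sum(enc2$net$transitions$automaton == "_goal"), 2)

  # no targets: the goal state is unreachable by construction
  enc0 <- encode_goal_states(fx$net, list())
  expect_equal(sum(enc0$net$transitions$automaton == "_goal"), 0)
  g <- reachable_graph(enc0$net, c(fx$initial, "_goal" = 0L))
  expect_equal(nrow(goal_connected(g, enc0$goal)), 0)

  expect_error(encode_goal_states(fx$net, list(), name = "a"),
               class = "an_semantic_error")
})

test_that("Boolean encoding produces prime-implicant transitions", {
  net <- encode_boolean_network(c(
    "targets, factors",
    "x, a & !b",
    "a, a",
    "b, b"
  ))
  xt <- net$transitions[net$transitions$automaton == "x", ]
  up <- xt[xt$origin == 0, ]
  down <- xt[xt$origin == 1, ]
  expect_equal(up$condition, list(c(a = 1L, b = 0L)))
  expect_setequal(
    vapply(down$condition, function(cc) paste0(names(cc), "=", cc),
           character(1)),
    c("a=0", "b=1")
  )
  # self-sustaining node: no transitions at all
  expect_equal(sum(net$transitions$automaton %in% c("a", "b")), 0)

  # tautology gives a single unconditioned activation
  net1 <- encode_boolean_network(c("targets, factors", "x, 1", "y, y"))
  xt1 <- net1$transitions[net1$transitions$automaton == "x", ]
  expect_equal(nrow(xt1), 1)
  expect_equal(c(xt1$origin, xt1$dest), c(0L, 1L))
  expect_length(xt1$condition[[1]], 0)

  # Boolean encodings only move one level at a time
  expect_true(all(abs(net$transitions$origin - net$transitions$dest) == 1))

  expect_error(encode_boolean_network(c("targets, factors", "x, z & x")),
               "unknown node", class = "an_parse_error")
  expect_error(encode_boolean_network(c("targets, factors", "x, a ^ b",
                                        "a, 1", "b, 1")),
               class = "an_parse_error")
})

test_that("Boolean encoding preserves the asynchronous state graph", {
  bns <- list(
    c("x, !y", "y, x", "z, x & !z | y"),
    c("x, x | y", "y, !x & z", "z, !z"),
    c("p, q & r", "q, !p | r", "r, p & !q", "s, s | (p & r)")
  )
  for (rows in bns) {
    net <- encode_boolean_network(c("targets, factors", rows))
    exprs <- oracle_bn_exprs(rows)
    nodes <- names(net$automata)
    grid <- expand.grid(rep(list(0:1), length(nodes)))
    colnames(grid) <- nodes
    for (r in seq_len(nrow(grid))) {
      s <- an_state(net, stats::setNames(as.integer(grid[r, ]), nodes))
      succ_an <- sort(unique(vapply(enabled(net, s)$id, function(tid) {
        format_an_state(apply_transition(net, s, tid))
      }, character(1))), method = "radix")
      succ_bn <- sort(unique(vapply(oracle_bn_successors(exprs, s),
                                    format_an_state, character(1))),
                      method = "radix")
      expect_identical(unname(succ_an), succ_bn)
    }
  }
})
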
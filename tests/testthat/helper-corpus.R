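# The random-network corpus used by the property-based tests: 200 seeded
# networks, 2-5 automata (cycling with the seed), 2-3 states per automaton,
# 1-3 transitions per automaton, condition sizes 0-2. State spaces are at
# most 3^5 = 243 states, so every instance is exhaustively checkable.

corpus_seeds <- 0:199

corpus_net <- function(seed) {
  random_an(
    n_automata = 2 + (seed %% 4),
    states = 2:3,
    transitions = 1:3,
    condition_size = 0:2,
    seed = seed
  )
}

# two deterministic goals per network for the bifurcation-soundness checks:
# the top local state of the first and of the last automaton
corpus_goals <- function(net) {
  autos <- names(net$automata)
  a1 <- autos[1]
  a2 <- autos[length(autos)]
  list(
    an_goal(a1, max(net$automata[[a1]])),
    an_goal(a2, max(net$automata[[a2]]))
  )
}

# a two-automaton toggle whose four states form one big cycle (no exit):
# the whole reachable graph is a single attractor
toggle_net <- function() {
  parse_an(c(
    'automaton "x" [0, 1]',
    'automaton "y" [0, 1]',
    '"x" 0 -> 1 when "y"=0',
    '"x" 1 -> 0 when "y"=1',
    '"y" 0 -> 1 when "x"=1',
    '"y" 1 -> 0 when "x"=0',
    'initial "x"=0, "y"=0'
  ))
}
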
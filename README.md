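# bifan — bifurcation transitions in asynchronous automata networks

Qualitative models of regulatory and signalling networks (Boolean and
multi-valued networks, and more generally *automata networks*) describe a
cell's dynamics as non-deterministic walks through a finite state space.
Differentiation shows up in these models as **bifurcation transitions**:
local transitions whose occurrence moves the system from a state where a
goal local state (say, the active form of a master regulator) is still
reachable into a state where it never can be reached again. Finding them
tells a modeller *when and how* the dynamics commits to one attractor over
another. `bifan` is for systems biologists and modellers who work with such
discrete networks and want those decisive transitions identified formally.

## The model and the method

An automata network is a tuple (Σ, S, T): a set of finite automata, each
with local states `a_0 … a_k−1`, and local transitions
`a_i → a_j when b_x, c_y, …` conditioned on the local states of *other*
automata. Under the asynchronous semantics one enabled transition fires at a
time. Given an initial state `s0` and a goal local state `g1`, a transition
`t_b` is a bifurcation transition when there are states `s_b → s_u = s_b·t_b`
with `s0 →* s_b`, the goal reachable from `s_b`, and unreachable from `s_u`.

`bifan` identifies them two ways:

* **exact** — build the reachable state graph, compute the set of states
  still connected to the goal by backward closure, and read off the
  transitions labelling edges that cross out of that set. Sound and
  complete, but limited by state-space size.
* **approximate (`I3` / `I3sharp`)** — never inspect most of the state
  space. Candidate `(t_b, s_b, s_u)` triples are screened with two static
  analyses over the *Local Causality Graph* (a tripartite digraph of local
  states, objectives `a_i ↝ a_j`, and acyclic within-automaton local paths):
  a necessary condition (a least fixpoint over objectives) must *refute* the
  goal from `s_u`, and a sufficient condition (an acyclic sub-graph witness,
  checked realizable by replaying its own transitions) must *certify* the
  goal from `s_b`. Reachability of `s_b` from `s0` uses either the explicit
  reachable set (`I3`) or another sufficient-condition witness (`I3sharp`,
  fully static). Every reported transition is a true bifurcation (no false
  positives); some may be missed.

## Worked example

The built-in three-automaton model (automata `a`, `b`, `c`; 8 local
transitions; initial state `⟨a0,b0,c0⟩`; goal `a=2`):

```r
library(bifan)

fx <- an_builtin("fig1")
enabled(fx$net, fx$initial)$id
#> [1] "t2" "t3" "t4"

g <- reachable_graph(fx$net, fx$initial)
g
#> Reachable state graph: 14 states, 26 transitions
#> root: a=0,b=0,c=0

attractors(g)
#> # A tibble: 2 × 3
#>   attractor  size states
#>       <int> <int> <list>
#> 1         1     4 <chr [4]>
#> 2         2     1 <chr [1]>

exact_bifurcations(fx$net, fx$initial, fx$goal)$transition
#> [1] "t8"

find_bifurcations(fx$net, fx$initial, fx$goal, mode = "I3sharp") |> tidy()
#> # A tibble: 1 × 4
#>   transition method  s_b           s_u
#>   <chr>      <chr>   <chr>         <chr>
#> 1 t8         I3sharp a=0,b=0,c=1   a=0,b=0,c=2
```

Three transitions are applicable in the initial state. The reachable graph
has 14 states and two attractors: a single state containing the goal `a=2`,
and a 4-state cycle from which the goal is lost. `t8` (`c: 1 -> 2 when b=0`)
is the unique bifurcation transition: firing it in `⟨a0,b0,c1⟩` traps
automaton `c` in state 2, after which `a=2` (which needs `c=0`) is
unreachable — and both approximate modes recover it without a false
positive.

There is also a command-line interface (installed under `exec/`):

```sh
bifan bifurcations model.an --initial "a=0,b=0,c=0" --goal "a=2" --method i3 --json
bifan gen-random --seed 7 --n-automata 4
```

## Further reading

The methods vignette (`vignettes/bifurcation-analysis.Rmd`) documents the
semantics, both approximations and their one-sidedness, the design choices
in the sufficient-condition search, what the random-network generator
emulates, and the limits of what the test corpus shows about real models.
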
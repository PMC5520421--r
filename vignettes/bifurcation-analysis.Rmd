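---
title: "Identifying bifurcation transitions in asynchronous automata networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying bifurcation transitions in asynchronous automata networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifan)
```

## The model

An automata network couples finite-state machines through conditioned local
transitions. Automaton `a` has local states `0 … k−1`; a transition
`a: i -> j when b=x, c=y` may fire in a global state `s` when `s(a) = i` and
every condition holds; firing replaces only the `a` coordinate. The
semantics is asynchronous: exactly one enabled transition fires per step,
chosen non-deterministically. This is the natural common ground for Boolean
and multi-valued (Thomas) regulatory models, which `encode_boolean_network()`
translates exactly (their asynchronous state graphs coincide with the
encoding's, a property the test suite checks against a truth-table oracle on
small networks).

A *goal* is a single local state `g1`; sets of goal states are reduced to
this case by `encode_goal_states()`, which adds a fresh two-state automaton
activated by each desired target assignment. An *attractor* is a set of
global states that is strongly connected and terminal under reachability —
the long-run behaviours. Given an initial state `s0`, a *bifurcation
transition* `t_b` admits reachable states `s_b` and `s_u = s_b · t_b` such
that the goal is reachable from `s_b` but from `s_u` it never is again. Such
transitions are where a differentiation decision is actually taken.

```{r}
fx <- an_builtin("fig1")
fx$net
```

## Exact identification

With the reachable state graph in hand the problem is linear: compute the
backward closure of the goal-containing states (`goal_connected()`); the
bifurcation transitions are exactly the labels of edges leaving that set.

```{r}
g <- reachable_graph(fx$net, fx$initial)
exact_bifurcations(fx$net, fx$initial, fx$goal)
```

`reachable_graph()` takes a `state_cap` (default 1,000,000 states) and
raises a typed error beyond it; the cap signals that a model needs the
approximate pipeline rather than silently truncating the graph. Insertion
order is breadth-first with transitions in id order, so graphs, attractor
ids and witness enumerations are deterministic.

## Static approximations

Reachability in asynchronous networks is expensive (PSPACE-complete in
general), so the approximate pipeline replaces it with two one-sided
analyses over the *Local Causality Graph* (LCG). An *objective* `a_i ~> a_j`
asks automaton `a` to move from `i` to `j`; its *local paths* are the
acyclic transition chains realizing it inside `a` alone (`local_paths()`),
and each path drags in the union of its conditions (`enab_of_path()`). The
LCG wires local states to the objectives ending at them, objectives to their
paths, and paths to their condition states (`build_lcg()`). Its size is
polynomial in the number of local transitions for the small per-automaton
state counts (2–4) typical of biological models, which is what makes the
whole approach scale where state graphs do not.

**Necessary condition (`oa_reach`).** The least fixpoint of
`F(Ω) = { a_i ~> a_j : some local path τ of a_i ~> a_j has s(b) ~> b_k ∈ Ω
for every condition b_k of τ }` collects every objective not refutable by
local-path structure. If the goal objective `s(g) ~> g1` is *not* in the
fixpoint, the goal is certainly unreachable; membership proves nothing. The
iteration only ever consults objectives rooted at coordinates of `s`, so it
runs on the lazily built cone of the LCG.

**Sufficient condition (`ua_reach`).** A witness is an acyclic sub-LCG in
which every included objective resolves to exactly one chosen local path,
every chosen path includes all its condition states, and every included
local state carries the objectives from the chosen context state of its
automaton and from the other included states of the same automaton. Two
further conditions close the gaps the tripartite structure leaves open:

* a per-step independence condition: within one transition's condition set,
  at most one local state whose sibling conditions' forward cones touch its
  automaton elsewhere;
* a realizability replay: the witness's own chosen transitions form a tiny
  sub-network of the model, and a breadth-first search inside it must
  actually drive the chosen context state to all targets simultaneously.

The replay deserves a note, because it is a design decision taken where the
design was genuinely open. Purely structural formulations of the sufficient
condition differ in how pairwise objectives between included states of one
automaton are quantified; the strongest quantification (both directions
between *all* pairs) rejects valid witnesses whenever a goal state has no
outgoing transitions, while weaker ones cannot express orderings in which an
automaton must revisit a state after one of its consumers has fired. Rather
than tune the quantifier, `bifan` requires witnesses to be constructive: any
execution found in the witness's own sub-network is an execution of the full
model, so a returned witness is a proof of reachability by replay, whatever
the structural reading missed. The cost is bounded by the product of the
involved automata's sizes — in practice a handful of transitions — and a
witness search remains a backtracking over context-state and path choices
(automata lexicographic, paths by length then step ids; first witness
returned). Absence of a witness still proves nothing, as the condition is
sufficient only:

```{r}
w <- ua_reach(fx$net, an_state(fx$net, "a=0,b=1,c=1"), c(a = 2L))
w
validate_ua_witness(w, an_state(fx$net, "a=0,b=1,c=1"), c(a = 2L))
```

The two analyses sandwich the truth — a sufficient-condition witness implies
real reachability implies the necessary condition holds — and the test suite
verifies that sandwich exhaustively on the random corpus described below.

## Approximate bifurcation search

`find_bifurcations()` screens each local transition `t`: the transition
forces the coordinates of `s_u` at its own automaton (destination) and its
condition automata; the remaining *free* automata are enumerated over their
domains (the goal automaton never takes the goal value, so `s_u` cannot
already contain the goal). An assignment is accepted when

1. the necessary condition *refutes* the goal from `s_u` (cheap fixpoint,
   checked first to fail fast),
2. `s_b` (= `s_u` with the transition's automaton reset to its origin) is
   reachable from `s0` — by membership in the explicit reachable set
   (mode `I3`) or by a sufficient-condition witness for reaching all of
   `s_b`'s coordinates simultaneously (mode `I3sharp`), and
3. a sufficient-condition witness certifies the goal from `s_b`.

Refutation from `s_u` and certification from `s_b` imply the bifurcation
property, so results are sound in both modes: no false positive is possible.
Completeness is deliberately given up — both the necessary and the
sufficient condition can be inconclusive — and mode `I3sharp`, which never
touches the state space, may miss more than `I3`. No per-instance ordering
between the two modes' result sizes is guaranteed, only soundness of each.
`classify_modes()` runs exact and both modes side by side:

```{r}
classify_modes(fx$net, fx$initial, fx$goal)
```

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `state_cap` | `reachable_graph`, exact/`I3` searches | 1e6 states | abort explicit enumeration; typed error signals "use `I3sharp`" |
| `mode` | `find_bifurcations` | `I3` | reachability certificate for `s_b` (explicit set vs static witness) |
| `all_witnesses` | `find_bifurcations` | `FALSE` | keep every `(s_b, s_u)` pair per transition instead of the first |
| `witnesses` | `exact_bifurcations` | `TRUE` | attach all crossing state pairs (disable on large graphs) |
| generator arguments | `random_an` | 3 automata, 2–3 states, 1–3 transitions, conditions 0–2 | shape of random test networks |

## What the random generator emulates — and what it does not

`random_an()` draws networks with a handful of automata, 2–3 local states
each, sparse transition sets and small conditions: the shape (small automata,
sparse coupling) of discrete biological models, at a scale where every
property remains exhaustively checkable. The pinned test corpus is 200 such
networks (seeds 0–199, 2–5 automata cycling with the seed), each with at
most 3^5 = 243 reachable states; an md5 manifest under `inst/extdata/`
guards against generator drift. On this corpus the test suite checks, for
*every* reachable state and goal: the sandwich above, agreement of the exact
bifurcation oracle with a direct evaluation of its temporal-logic
characterization, soundness of both approximate modes, and that nonempty
bifurcation sets imply a goal-free attractor.

Random networks are not biology: they lack the regulatory structure
(feedback circuits, signalling cascades, canalizing update functions) and
the scale (hundreds of automata) of curated models, and their conditions are
drawn independently rather than from a wiring diagram. Passing tests
therefore demonstrate *correctness* of the algorithms on exhaustively
checkable instances, not *performance or yield* on large real models — for
those, the approximate modes' false-negative rate depends on how much
concurrency and reconvergence the model exhibits, which the corpus does not
emulate. Published case-study models can be dropped into
`tests/testthat/casestudies/` to run the optional regression checks.

## Numerical and degenerate-input choices

* State indices are 0-based; automata are ordered lexicographically, making
  state serialization (`"a=0,b=1,c=0"`) canonical and reports byte-stable.
* Prime implicants in the Boolean encoding are enumerated by truth-table
  minimization, ordered by literal count then lexicographically; a node's
  own literal is removed by restricting the function before minimization, so
  self-conditions never appear. Any implicant cover is dynamically
  equivalent; primes make the encoding canonical and minimal.
* An objective `a_i ~> a_i` has exactly the empty path; a goal already in
  the queried state is certified by it (reachability is reflexive).
* Empty target sets in `encode_goal_states()` are legal and produce an
  unreachable goal, which every search then reports as bifurcation-free.
* Transitions with no out-paths (dead-end local states) simply yield empty
  local-path sets; the fixpoint and witness search treat them as refuting.
* The witness search memoizes local-path enumeration per network; batch
  callers can share the cache across queries.

## Known limitations

* The sufficient condition is incomplete by design; on models whose
  reachability hinges on transition orderings invisible to the LCG, the
  approximate modes report fewer bifurcations than the exact oracle (never
  more). The replay filter also rejects structurally valid witnesses whose
  sub-network exceeds its search cap, again erring on the sound side.
* Exact mode stores the full edge list; models beyond a few million
  reachable states need `I3sharp`.
* Only asynchronous semantics is implemented; synchronous or mixed update
  schemes, and universal/existential bifurcations over sets of initial
  states, are out of scope.
* The `.an` dialect parsed here is the package's canonical format;
  interoperability with other tools' automata-network dialects is not
  promised.
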
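#' Seeded random automata networks
#'
#' Generates a random automata network for property-based testing:
#' `n_automata` automata named `a, b, c, ...`, each with a number of local
#' states drawn from `states`, each with a number of local transitions drawn
#' from `transitions`, whose origin/destination are distinct local states and
#' whose condition draws a size from `condition_size` and then that many
#' distinct *other* automata, one random local state each. The generator is
#' deterministic for a fixed seed and restores the caller's RNG state.
#'
#' @param n_automata Number of automata (>= 2).
#' @param states Integer vector of allowed per-automaton state counts.
#' @param transitions Integer vector of allowed per-automaton transition
#'   counts.
#' @param condition_size Integer vector of allowed condition sizes; sizes are
#'   truncated to `n_automata - 1`.
#' @param seed Integer seed.
#' @return An `an` object with a random declared initial state.
#' @examples
#' random_an(seed = 42)
#' @export
random_an <- function(n_automata = 3, states = 2:3, transitions = 1:3,
                      condition_size = 0:2, seed = 1) {
  if (n_automata < 2) {
    an_error("n_automata must be >= 2", "an_semantic_error")
  }
  if (min(condition_size) > n_automata - 1) {
    an_error("condition_size infeasible: conditions draw from other automata",
             "an_semantic_error")
  }
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  name_of <- function(i) {
    # a, b, ..., z, aa, ab, ...
    out <- ""
    i <- i - 1L
    repeat {
      out <- paste0(letters[i %% 26L + 1L], out)
      i <- i %/% 26L - 1L
      if (i < 0) break
    }
    out
  }
  autos <- map_chr(seq_len(n_automata), name_of)

  pick <- function(v) if (length(v) == 1) v else sample(v, 1)
  n_states <- stats::setNames(
    map_int(seq_len(n_automata), function(i) as.integer(pick(states))),
    autos
  )

  rows <- list()
  for (a in autos) {
    for (k in seq_len(pick(transitions))) {
      od <- sample.int(n_states[[a]], 2) - 1L
      csz <- min(pick(condition_size), n_automata - 1L)
      cond <- integer(0)
      if (csz > 0) {
        others <- setdiff(autos, a)
        picked <- if (length(others) == 1) others else sample(others, csz)
        cond <- stats::setNames(
          map_int(picked, function(b) sample.int(n_states[[b]], 1) - 1L),
          picked
        )
      }
      rows[[length(rows) + 1L]] <- list(
        automaton = a, origin = od[1], dest = od[2], condition = cond
      )
    }
  }

  initial <- stats::setNames(
    map_int(autos, function(a) sample.int(n_states[[a]], 1) - 1L), autos
  )

  an_network(
    automata = as.list(n_states),
    transitions = tibble(
      automaton = map_chr(rows, "automaton"),
      origin = map_int(rows, "origin"),
      dest = map_int(rows, "dest"),
      condition = map(rows, "condition")
    ),
    initial = initial
  )
}

#' Built-in models
#'
#' `"fig1"` is the three-automaton worked example used throughout the
#' documentation: automata `a` (3 states), `b` (2 states), `c` (3 states) and
#' 8 local transitions
#' \preformatted{
#' t1: a 1 -> 0        t4: b 0 -> 1          t6: c 0 -> 1 when a=1
#' t2: a 0 -> 1 when b=0   t5: b 1 -> 0 when a=0   t7: c 1 -> 0 when b=1
#' t3: a 0 -> 2 when b=0, c=0                      t8: c 1 -> 2 when b=0
#' }
#' with initial state `<a0, b0, c0>` and goal `a=2`. Once automaton `c`
#' reaches state 2 it can never leave it, and `a` can only reach state 2
#' while `c` is at 0: transition `t8` is the unique bifurcation transition
#' for the goal.
#'
#' @param name Model name; only `"fig1"` is built in.
#' @return A list with `net` (an `an`), `initial` (global state) and `goal`
#'   (an [an_goal()]).
#' @examples
#' fx <- an_builtin("fig1")
#' fx$net
#' @export
an_builtin <- function(name = "fig1") {
  if (!identical(name, "fig1")) {
    an_error(paste0("unknown builtin model: ", name), "an_semantic_error")
  }
  net <- parse_an(c(
    'automaton "a" [0, 1, 2]',
    'automaton "b" [0, 1]',
    'automaton "c" [0, 1, 2]',
    '"a" 1 -> 0',
    '"a" 0 -> 1 when "b"=0',
    '"a" 0 -> 2 when "b"=0, "c"=0',
    '"b" 0 -> 1',
    '"b" 1 -> 0 when "a"=0',
    '"c" 0 -> 1 when "a"=1',
    '"c" 1 -> 0 when "b"=1',
    '"c" 1 -> 2 when "b"=0',
    'initial "a"=0, "b"=0, "c"=0'
  ))
  list(net = net, initial = net$initial, goal = an_goal("a", 2L))
}
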
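# Compiled form of a network for fast repeated simulation: positional
# indices instead of names. Cached inside analysis loops.
an_compile <- function(net) {
  autos <- names(net$automata)
  pos <- stats::setNames(seq_along(autos), autos)
  tr <- net$transitions
  list(
    autos = autos,
    pos = pos,
    n_states = map_int(net$automata, length),
    trans = lapply(seq_len(nrow(tr)), function(r) {
      cond <- tr$condition[[r]]
      list(
        id = tr$id[r],
        a = pos[[tr$automaton[r]]],
        i = tr$origin[r],
        j = tr$dest[r],
        cpos = unname(pos[names(cond)]),
        cval = unname(cond)
      )
    })
  )
}

enabled_idx <- function(comp, s) {
  keep <- logical(length(comp$trans))
  for (k in seq_along(comp$trans)) {
    t <- comp$trans[[k]]
    keep[k] <- s[[t$a]] == t$i &&
      (length(t$cpos) == 0L || all(s[t$cpos] == t$cval))
  }
  which(keep)
}

#' Transitions applicable in a global state
#'
#' A local transition `a_i -> a_j when l` is applicable (enabled) in global
#' state `s` when `s(a) = i` and every local state in the condition `l` is in
#' `s`.
#'
#' @param net An `an` object.
#' @param s A global state (see [an_state()]); also accepts the string form.
#' @return The subset of `net$transitions` (a tibble) enabled in `s`, in id
#'   order.
#' @examples
#' fx <- an_builtin("fig1")
#' enabled(fx$net, fx$initial)$id
#' @export
enabled <- function(net, s) {
  stopifnot(inherits(net, "an"))
  s <- an_state(net, s)
  comp <- an_compile(net)
  net$transitions[enabled_idx(comp, unname(s)), ]
}

#' Apply one local transition (asynchronous step)
#'
#' @param net An `an` object.
#' @param s A global state.
#' @param t A transition id (e.g. `"t4"`) or a one-row slice of
#'   `net$transitions`.
#' @return The successor global state: `s` with the transition's automaton
#'   moved to its destination local state. Errors (class
#'   `an_not_applicable`) when `t` is not enabled in `s`.
#' @examples
#' fx <- an_builtin("fig1")
#' apply_transition(fx$net, fx$initial, "t4")
#' @export
apply_transition <- function(net, s, t) {
  stopifnot(inherits(net, "an"))
  s <- an_state(net, s)
  if (is.character(t)) {
    r <- which(net$transitions$id == t)
    if (length(r) != 1) an_error(paste0("unknown transition id: ", t),
                                 "an_semantic_error")
    t <- net$transitions[r, ]
  }
  a <- t$automaton[[1]]
  cond <- t$condition[[1]]
  ok <- s[[a]] == t$origin[[1]] &&
    (length(cond) == 0 || all(s[names(cond)] == cond))
  if (!ok) {
    an_error(paste0("transition ", t$id[[1]], " not applicable in state ",
                    format_an_state(s)), "an_not_applicable")
  }
  s[[a]] <- t$dest[[1]]
  s
}

#' Encode a set of goal states as a fresh goal automaton
#'
#' Reachability of a *set* of global (or partial) target states reduces to
#' reachability of a single goal local state: a fresh two-state automaton `g`
#' (initially 0) is added, with one transition `g: 0 -> 1` conditioned by
#' each target assignment. The goal becomes `g = 1`.
#'
#' @param net An `an` object.
#' @param targets A list of partial state assignments (named integer vectors,
#'   or strings like `"CI=2,Cro=0"`). May be empty, in which case the goal is
#'   unreachable by construction.
#' @param name Name for the fresh automaton (default `"_goal"`). Errors if it
#'   clashes with an existing automaton.
#' @return A list with elements `net` (the extended network) and `goal` (an
#'   [an_goal()] for the fresh automaton at state 1).
#' @examples
#' fx <- an_builtin("fig1")
#' gs <- encode_goal_states(fx$net, list(c(a = 2L, b = 1L)))
#' gs$goal
#' @export
encode_goal_states <- function(net, targets, name = "_goal") {
  stopifnot(inherits(net, "an"))
  if (name %in% names(net$automata)) {
    an_error(paste0("goal automaton name clashes with existing automaton ",
                    name), "an_semantic_error")
  }
  targets <- lapply(targets, function(tg) {
    if (is.character(tg) && length(tg) == 1) tg <- parse_assignments(tg)
    for (b in names(tg)) {
      if (!b %in% names(net$automata) || !(tg[[b]] %in% net$automata[[b]])) {
        an_error(paste0("target references undeclared local state ",
                        b, "=", tg[[b]]), "an_semantic_error")
      }
    }
    stats::setNames(as.integer(tg), names(tg))
  })

  tr <- net$transitions
  n0 <- nrow(tr)
  ids <- paste0("t", n0 + seq_along(targets))
  if (any(ids %in% tr$id)) ids <- paste0("goal_t", seq_along(targets))
  new_rows <- if (length(targets)) {
    tibble(
      id = ids,
      automaton = name,
      origin = 0L, dest = 1L,
      condition = targets
    )
  } else {
    NULL
  }
  automata <- c(net$automata, stats::setNames(list(0:1), name))
  initial <- if (!is.null(net$initial)) {
    c(net$initial, stats::setNames(0L, name))
  } else {
    NULL
  }
  out <- an_network(automata, dplyr::bind_rows(tr, new_rows))
  if (!is.null(initial)) out$initial <- an_state(out, initial)
  list(net = out, goal = an_goal(name, 1L))
}
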
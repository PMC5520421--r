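#' Reachability over-approximation (necessary condition)
#'
#' Computes the least fixpoint of the monotone operator over objectives
#' \deqn{F(\Omega) = \{ a_i \leadsto a_j : \exists \tau \in
#'   local\mbox{-}paths(a_i \leadsto a_j), \forall b_k \in enab(\tau),
#'   s(b) \leadsto b_k \in \Omega \}}{F(Omega)}
#' and decides whether the goal objective `s(g) ~> g_1` belongs to it. A
#' `FALSE` decision certifies that no state containing the goal is reachable
#' from `s`; a `TRUE` decision certifies nothing (the condition is necessary,
#' not sufficient). Only objectives rooted at the local states of `s` can
#' ever enter the fixpoint, so the iteration runs over the lazily built,
#' root-directed portion of the Local Causality Graph.
#'
#' @param net An `an` object.
#' @param s Global state to start from.
#' @param goal An [an_goal()] (or string `"a=2"`).
#' @param cache Optional memoization environment from an earlier call on the
#'   same network (see [lp_cache]); reuse speeds up batch queries.
#' @return An object of class `an_oa`: list with `decision` (logical) and
#'   `omega` (tibble of objectives in the fixpoint: `automaton`, `from`,
#'   `to`).
#' @examples
#' fx <- an_builtin("fig1")
#' oa_reach(fx$net, an_state(fx$net, "a=1,b=0,c=2"), fx$goal)$decision
#' oa_reach(fx$net, an_state(fx$net, "a=1,b=0,c=1"), fx$goal)$decision
#' @export
oa_reach <- function(net, s, goal, cache = NULL) {
  stopifnot(inherits(net, "an"))
  s <- an_state(net, s)
  goal <- check_goal(net, goal)
  if (is.null(cache)) cache <- lp_cache(net)

  # objectives of interest all have the form s(b) ~> b_k: identify them by
  # (automaton, target index)
  root <- c(goal$automaton, goal$index)

  # collect the closure of potentially relevant objectives
  pending <- list(root)
  seen <- new.env(parent = emptyenv())
  objs <- list()
  while (length(pending)) {
    cur <- pending[[length(pending)]]
    pending[[length(pending)]] <- NULL
    key <- paste0(cur[1], "=", cur[2])
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    a <- cur[1]; j <- as.integer(cur[2])
    objs[[key]] <- list(automaton = a, to = j)
    for (p in cached_local_paths(cache, a, s[[a]], j)) {
      enab <- p$enab
      for (ii in seq_along(enab)) {
        pending[[length(pending) + 1L]] <- c(names(enab)[ii], enab[[ii]])
      }
    }
  }

  # chaotic iteration to the least fixpoint
  in_omega <- stats::setNames(rep(FALSE, length(objs)), names(objs))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (key in names(objs)) {
      if (in_omega[[key]]) next
      a <- objs[[key]]$automaton; j <- objs[[key]]$to
      for (p in cached_local_paths(cache, a, s[[a]], j)) {
        enab <- p$enab
        ok <- TRUE
        for (ii in seq_along(enab)) {
          if (!in_omega[[paste0(names(enab)[ii], "=", enab[[ii]])]]) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          in_omega[[key]] <- TRUE
          changed <- TRUE
          break
        }
      }
    }
  }

  omega_keys <- names(in_omega)[in_omega]
  omega <- if (length(omega_keys)) {
    tibble(
      automaton = map_chr(objs[omega_keys], "automaton"),
      from = map_int(objs[omega_keys], function(o) s[[o$automaton]]),
      to = map_int(objs[omega_keys], "to")
    )
  } else {
    tibble(automaton = character(0), from = integer(0), to = integer(0))
  }
  structure(
    list(decision = in_omega[[paste0(goal$automaton, "=", goal$index)]],
         omega = omega, state = s, goal = goal),
    class = "an_oa"
  )
}

#' @export
print.an_oa <- function(x, ...) {
  cat("Reachability over-approximation from", format_an_state(x$state),
      "to", paste0(x$goal$automaton, "=", x$goal$index), "\n")
  cat(if (x$decision) {
    "necessary condition satisfied (reachability NOT disproved)\n"
  } else {
    "necessary condition violated: goal is UNREACHABLE\n"
  })
  cat("fixpoint size:", nrow(x$omega), "objectives\n")
  invisible(x)
}

#' Reachability context
#'
#' A context generalizes a global state: each automaton is mapped to a
#' non-empty set of possible local states. A global state is the special
#' case of singleton sets.
#'
#' @param net An `an` object.
#' @param allowed Named list mapping automaton to an integer vector of
#'   allowed local-state indices; automata left out default to their full
#'   domain. A named integer vector (a global state) is also accepted.
#' @return Named list, one sorted integer vector per automaton of `net`.
#' @examples
#' fx <- an_builtin("fig1")
#' an_context(fx$net, fx$initial)            # singleton context
#' an_context(fx$net, list(a = c(0L, 1L)))   # a free over {0,1}, rest full
#' @export
an_context <- function(net, allowed = list()) {
  stopifnot(inherits(net, "an"))
  if (!is.list(allowed)) allowed <- as.list(allowed)
  ctx <- list()
  for (a in names(net$automata)) {
    v <- allowed[[a]] %||% net$automata[[a]]
    v <- sort(unique(as.integer(v)))
    if (length(v) == 0 || !all(v %in% net$automata[[a]])) {
      an_error(paste0("context for ", a, " must be a non-empty set of ",
                      "declared local states"), "an_semantic_error")
    }
    ctx[[a]] <- v
  }
  ctx
}

# --- Under-approximation -----------------------------------------------------

# Realizability replay: the decisive filter of the sufficient condition.
# A structurally valid sub-LCG fixes a set of chosen local transitions and a
# chosen context state per automaton; the dynamics restricted to exactly
# those transitions is a (tiny) sub-network of the model, so any execution
# found inside it is an execution of the model. The witness is accepted only
# if a breadth-first search over that sub-network reaches a state containing
# all targets simultaneously. This guards against orderings the tripartite
# graph cannot express (an automaton having to revisit a state after one of
# its consumers fired).
ua_replay <- function(net, chosen_steps, ctx_choice, targets,
                      cap = 50000) {
  autos <- names(ctx_choice)
  s0 <- stats::setNames(as.integer(ctx_choice[autos]), autos)
  rows <- match(unique(chosen_steps), net$transitions$id)
  tr <- net$transitions[rows, , drop = FALSE]
  hit <- function(s) all(s[names(targets)] == targets)
  if (hit(s0)) return(TRUE)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  queue <- list(s0)
  assign(paste(s0, collapse = ","), TRUE, envir = seen)
  n <- 1L
  while (length(queue)) {
    s <- queue[[1]]
    queue <- queue[-1]
    for (r in seq_len(nrow(tr))) {
      if (s[[tr$automaton[r]]] != tr$origin[r]) next
      cond <- tr$condition[[r]]
      ok <- TRUE
      for (b in names(cond)) if (s[[b]] != cond[[b]]) { ok <- FALSE; break }
      if (!ok) next
      s2 <- s
      s2[[tr$automaton[r]]] <- tr$dest[r]
      key <- paste(s2, collapse = ",")
      if (!is.null(seen[[key]])) next
      if (hit(s2)) return(TRUE)
      n <- n + 1L
      if (n > cap) {
        warn("under-approximation replay cap exceeded; witness rejected")
        return(FALSE)
      }
      assign(key, TRUE, envir = seen)
      queue[[length(queue) + 1L]] <- s2
    }
  }
  FALSE
}

#' Reachability under-approximation (sufficient condition)
#'
#' Searches for a sub-graph of the Local Causality Graph witnessing the
#' simultaneous reachability of the target local states from the context:
#' every included objective owns exactly one chosen local path, every chosen
#' path pulls in all the local states of its condition union, every included
#' local state requires the objective from the chosen context state of its
#' automaton and from every other included (non-target) local state of the
#' same automaton, and the resulting graph must be acyclic and satisfy the
#' per-step condition-independence requirement. Finally the witness must be
#' *realizable*: restricted to the witness's own chosen transitions (a tiny
#' sub-network of the model), some execution from the chosen context state
#' must reach all targets simultaneously; this closes ordering constraints
#' the tripartite structure cannot express and makes every returned witness
#' a constructive proof. A returned witness *proves*
#' that all targets are simultaneously reachable from any global state
#' compatible with the witness's chosen context states; absence of a witness
#' proves nothing.
#'
#' The search backtracks over the context-state choice per automaton and the
#' local-path choice per objective (automata in lexicographic order, paths by
#' length then step ids); the first witness in that order is returned.
#'
#' @param net An `an` object.
#' @param ctx A context from [an_context()], or a global state (singleton
#'   context).
#' @param targets Target local states: a named integer vector
#'   (`c(a = 2L)`), a string `"a=2,b=1"`, or a tibble with columns
#'   `automaton`, `index`.
#' @param cache Optional memoization environment (see [oa_reach()]).
#' @return `NULL` when no witness is found, else an object of class
#'   `an_ua_witness`: list with `context_choice` (named integer vector over
#'   the automata used), `chosen_paths` (named list objective key ->
#'   character vector of step ids), `local_states`, `edges` (tibble
#'   `from`, `to` over node keys) and `targets`.
#' @examples
#' fx <- an_builtin("fig1")
#' w <- ua_reach(fx$net, an_state(fx$net, "a=0,b=1,c=1"), c(a = 2L))
#' !is.null(w)
#' @export
ua_reach <- function(net, ctx, targets, cache = NULL) {
  stopifnot(inherits(net, "an"))
  if (!is.list(ctx)) ctx <- an_context(net, ctx)
  if (is.character(targets) && length(targets) == 1) {
    targets <- parse_assignments(targets)
  }
  if (is.data.frame(targets)) {
    targets <- stats::setNames(as.integer(targets$index), targets$automaton)
  }
  if (length(targets) == 0) {
    an_error("targets must be non-empty", "an_semantic_error")
  }
  for (ii in seq_along(targets)) {
    a <- names(targets)[ii]
    if (!a %in% names(net$automata) ||
        !(targets[[ii]] %in% net$automata[[a]])) {
      an_error(paste0("target references undeclared local state ",
                      a, "=", targets[[ii]]), "an_semantic_error")
    }
  }
  if (is.null(cache)) cache <- lp_cache(net)

  target_keys <- paste0(names(targets), "=", unname(targets))

  # search state: environment-free functional style; small graphs expected
  # st: list(ls = named int-ish list key -> c(automaton, index),
  #          ctx_choice = named int vector,
  #          objs = named list obj_key -> chosen path (list steps, enab) or NA,
  #          pending = character vector of obj keys awaiting a path choice,
  #          edges_from/edges_to)
  empty_state <- list(
    ls = list(), ctx_choice = stats::setNames(integer(0), character(0)),
    objs = list(), pending = character(0),
    edges_from = character(0), edges_to = character(0)
  )

  add_edge <- function(st, from, to) {
    st$edges_from <- c(st$edges_from, from)
    st$edges_to <- c(st$edges_to, to)
    st
  }

  # require objective (a: i ~> j) with edge from the local state a_j
  require_obj <- function(st, a, i, j) {
    ok <- obj_node_key(a, i, j)
    st <- add_edge(st, ls_key(a, j), ok)
    if (is.null(st$objs[[ok]])) {
      st$objs[[ok]] <- NA  # path not chosen yet
      st$pending <- c(st$pending, ok)
    }
    st
  }

  # add local state a_j (and its induced objective requirements); returns NULL
  # on definite failure (context automaton exhausted is handled by branching
  # in solve(), not here)
  add_ls_choices <- function(st, a, j) {
    lk <- ls_key(a, j)
    if (!is.null(st$ls[[lk]])) return(list(st))
    st$ls[[lk]] <- c(a, j)

    branches <- list()
    if (a %in% names(st$ctx_choice)) {
      branches <- list(st)
    } else {
      # branch on the context choice for automaton a (ascending order)
      for (v in ctx[[a]]) {
        st2 <- st
        st2$ctx_choice[[a]] <- v
        branches[[length(branches) + 1L]] <- st2
      }
    }

    out <- list()
    for (st2 in branches) {
      # context objective c(a) ~> a_j
      st2 <- require_obj(st2, a, st2$ctx_choice[[a]], j)
      # pairwise objectives with other included states of automaton a:
      # from every included non-target state to a_j, and from a_j (if not a
      # target) to every other included state
      for (lk2 in names(st2$ls)) {
        v <- st2$ls[[lk2]]
        if (v[1] != a || lk2 == lk) next
        i2 <- as.integer(v[2])
        if (!(lk2 %in% target_keys)) st2 <- require_obj(st2, a, i2, j)
        if (!(lk %in% target_keys)) st2 <- require_obj(st2, a, j, i2)
      }
      out[[length(out) + 1L]] <- st2
    }
    out
  }

  # order paths by (length, concatenated step ids)
  ordered_paths <- function(a, i, j) {
    ps <- cached_local_paths(cache, a, i, j)
    if (length(ps) <= 1) return(ps)
    keys <- map_chr(ps, function(p) {
      sprintf("%03d|%s", length(p$steps), paste(p$steps, collapse = ","))
    })
    ps[order(keys, method = "radix")]
  }

  final_check <- function(st) {
    # acyclicity over the witness digraph
    nodes <- unique(c(st$edges_from, st$edges_to))
    adj <- split(st$edges_to, factor(st$edges_from, levels = nodes))
    color <- stats::setNames(rep(0L, length(nodes)), nodes)
    dfs_stack_ok <- TRUE
    dfs <- function(v) {
      color[[v]] <<- 1L
      for (w in adj[[v]]) {
        if (color[[w]] == 1L) { dfs_stack_ok <<- FALSE; return() }
        if (color[[w]] == 0L) {
          dfs(w)
          if (!dfs_stack_ok) return()
        }
      }
      color[[v]] <<- 2L
    }
    for (v in nodes) {
      if (color[[v]] == 0L) {
        dfs(v)
        if (!dfs_stack_ok) return(FALSE)
      }
    }

    # per-step condition-independence: for every step of every chosen path,
    # at most one condition state a_i such that the other condition states'
    # forward-connected sets touch S(a) outside {a_i}
    conn_memo <- new.env(parent = emptyenv())
    forward_conn <- function(v) {
      got <- conn_memo[[v]]
      if (!is.null(got)) return(got)
      seen <- character(0)
      stack <- v
      while (length(stack)) {
        x <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        for (w in adj[[x]]) {
          if (is.null(w)) next
          if (!(w %in% seen)) {
            seen <- c(seen, w)
            stack <- c(stack, w)
          }
        }
      }
      assign(v, seen, envir = conn_memo)
      seen
    }
    for (ok in names(st$objs)) {
      chosen <- st$objs[[ok]]
      for (step_enab in chosen$step_enabs) {
        if (length(step_enab) < 2) next
        n_bad <- 0L
        for (ii in seq_along(step_enab)) {
          a_i <- names(step_enab)[ii]
          v_i <- step_enab[[ii]]
          all_disturb <- TRUE
          for (jj in seq_along(step_enab)) {
            if (jj == ii) next
            bk <- ls_key(names(step_enab)[jj], step_enab[[jj]])
            conn_ls <- forward_conn(bk)
            sa <- conn_ls[startsWith(conn_ls, paste0(a_i, "="))]
            if (length(setdiff(sa, ls_key(a_i, v_i))) == 0) {
              all_disturb <- FALSE
              break
            }
          }
          if (all_disturb) n_bad <- n_bad + 1L
        }
        if (n_bad > 1L) return(FALSE)
      }
    }
    TRUE
  }

  solve <- function(st) {
    if (length(st$pending) == 0) {
      if (final_check(st) &&
          ua_replay(net, unlist(lapply(st$objs, function(p) p$steps),
                                use.names = FALSE),
                    st$ctx_choice, targets[names(targets) %in%
                                             names(st$ctx_choice)])) {
        return(st)
      }
      return(NULL)
    }
    ok <- st$pending[[1]]
    st$pending <- st$pending[-1]
    m <- regmatches(ok, regexec("^(.*):([0-9]+)~>([0-9]+)$", ok, perl = TRUE))[[1]]
    a <- m[2]; i <- as.integer(m[3]); j <- as.integer(m[4])
    for (p in ordered_paths(a, i, j)) {
      st2 <- st
      st2$objs[[ok]] <- p
      pkey <- paste0(ok, "#", paste(p$steps, collapse = ";"))
      st2 <- add_edge(st2, ok, pkey)
      enab <- p$enab
      branchsets <- list(st2)
      failed <- FALSE
      for (ii in seq_along(enab)) {
        b <- names(enab)[ii]; k <- enab[[ii]]
        nxt <- list()
        for (stb in branchsets) {
          stb <- add_edge(stb, pkey, ls_key(b, k))
          nxt <- c(nxt, add_ls_choices(stb, b, k))
        }
        branchsets <- nxt
        if (length(branchsets) == 0) { failed <- TRUE; break }
      }
      if (failed) next
      for (stb in branchsets) {
        res <- solve(stb)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }

  # seed: all targets are root children
  sts <- list(empty_state)
  for (ii in seq_along(targets)) {
    nxt <- list()
    for (st in sts) {
      nxt <- c(nxt, add_ls_choices(st, names(targets)[ii], targets[[ii]]))
    }
    sts <- nxt
  }
  for (st in sts) {
    res <- solve(st)
    if (!is.null(res)) {
      chosen <- lapply(res$objs, function(p) p$steps)
      return(structure(
        list(
          context_choice = res$ctx_choice[order(names(res$ctx_choice),
                                                method = "radix")],
          chosen_paths = chosen,
          local_states = sort(names(res$ls), method = "radix"),
          edges = dplyr::distinct(tibble(from = res$edges_from,
                                         to = res$edges_to)),
          targets = stats::setNames(as.integer(targets), names(targets)),
          net = net
        ),
        class = "an_ua_witness"
      ))
    }
  }
  NULL
}

#' @export
print.an_ua_witness <- function(x, ...) {
  cat("Reachability under-approximation witness\n")
  cat("targets:", paste0(names(x$targets), "=", x$targets, collapse = ", "),
      "\n")
  cat("context choice:", paste0(names(x$context_choice), "=",
                                x$context_choice, collapse = ", "), "\n")
  cat("objectives resolved:", length(x$chosen_paths), "\n")
  invisible(x)
}

#' Independently re-validate an under-approximation witness
#'
#' Re-tests every structural clause of the sufficient condition on a witness
#' returned by [ua_reach()]: targets present, context and pairwise objectives
#' all required and resolved, chosen paths are genuine local paths whose
#' condition unions are fully included, the graph is acyclic, and the
#' per-step independence condition holds. Used by the test suite; exposed so
#' users can audit witnesses.
#'
#' @param w An `an_ua_witness`.
#' @param ctx The context the witness was searched under.
#' @param targets The targets it was searched for.
#' @return `TRUE` if every clause holds, otherwise `FALSE` (with a warning
#'   naming the failed clause).
#' @export
validate_ua_witness <- function(w, ctx, targets) {
  stopifnot(inherits(w, "an_ua_witness"))
  net <- w$net
  if (!is.list(ctx)) ctx <- an_context(net, ctx)
  if (is.character(targets) && length(targets) == 1) {
    targets <- parse_assignments(targets)
  }
  fail <- function(msg) { warn(paste0("witness invalid: ", msg)); FALSE }

  target_keys <- paste0(names(targets), "=", unname(targets))
  if (!all(target_keys %in% w$local_states)) {
    return(fail("missing target local state"))
  }
  for (a in names(w$context_choice)) {
    if (!(w$context_choice[[a]] %in% ctx[[a]])) {
      return(fail("context choice outside the allowed context"))
    }
  }

  # reconstruct required objectives
  by_autom <- split(w$local_states, sub("=.*$", "", w$local_states))
  required <- character(0)
  for (lk in w$local_states) {
    a <- sub("=.*$", "", lk)
    j <- as.integer(sub("^.*=", "", lk))
    if (!a %in% names(w$context_choice)) {
      return(fail("no context choice for a used automaton"))
    }
    required <- c(required, obj_node_key(a, w$context_choice[[a]], j))
    for (lk2 in by_autom[[a]]) {
      if (lk2 == lk) next
      i2 <- as.integer(sub("^.*=", "", lk2))
      if (!(lk2 %in% target_keys)) {
        required <- c(required, obj_node_key(a, i2, j))
      }
    }
  }
  required <- unique(required)
  if (!setequal(required, names(w$chosen_paths))) {
    return(fail("resolved objectives differ from the required set"))
  }

  cache <- lp_cache(net)
  for (ok in names(w$chosen_paths)) {
    m <- regmatches(ok, regexec("^(.*):([0-9]+)~>([0-9]+)$", ok, perl = TRUE))[[1]]
    ps <- cached_local_paths(cache, m[2], as.integer(m[3]), as.integer(m[4]))
    hit <- keep(ps, function(p) identical(p$steps, w$chosen_paths[[ok]]))
    if (length(hit) != 1) return(fail("chosen path is not a local path"))
    enab <- hit[[1]]$enab
    for (ii in seq_along(enab)) {
      if (!(ls_key(names(enab)[ii], enab[[ii]]) %in% w$local_states)) {
        return(fail("condition local state missing from the witness"))
      }
    }
  }

  # acyclicity via igraph (independent of the search's own DFS)
  nodes <- unique(c(w$edges$from, w$edges$to))
  ig <- igraph::graph_from_data_frame(w$edges, directed = TRUE,
                                      vertices = data.frame(name = nodes))
  if (!igraph::is_dag(ig)) return(fail("witness graph is cyclic"))

  # independence condition, recomputed from scratch
  adj <- split(w$edges$to, factor(w$edges$from, levels = nodes))
  forward_conn <- function(v) {
    seen <- character(0); stack <- v
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (nb in adj[[x]]) {
        if (!(nb %in% seen)) { seen <- c(seen, nb); stack <- c(stack, nb) }
      }
    }
    seen
  }
  # realizability: the sub-network made of the chosen transitions must
  # actually drive the chosen context state to all targets simultaneously
  # (checked here through the explicit state-graph machinery, a different
  # code path from the search's own replay)
  used_autos <- names(w$context_choice)
  chosen_ids <- unique(unlist(w$chosen_paths, use.names = FALSE))
  sub_tr <- net$transitions[net$transitions$id %in% chosen_ids, , drop = FALSE]
  sub_net <- an_network(net$automata[used_autos], sub_tr)
  sub_g <- reachable_graph(sub_net, w$context_choice[sort(used_autos,
                                                          method = "radix")])
  realized <- any(vapply(sub_g$states, function(s) {
    all(s[names(w$targets)] == w$targets)
  }, logical(1)))
  if (!realized) return(fail("witness is not realizable by its own steps"))

  for (ok in names(w$chosen_paths)) {
    steps <- w$chosen_paths[[ok]]
    for (tid in steps) {
      step_enab <- net$transitions$condition[[match(tid, net$transitions$id)]]
      if (length(step_enab) < 2) next
      n_bad <- 0L
      for (ii in seq_along(step_enab)) {
        a_i <- names(step_enab)[ii]
        all_disturb <- TRUE
        for (jj in seq_along(step_enab)) {
          if (jj == ii) next
          conn_ls <- forward_conn(ls_key(names(step_enab)[jj],
                                         step_enab[[jj]]))
          sa <- conn_ls[startsWith(conn_ls, paste0(a_i, "="))]
          if (length(setdiff(sa, ls_key(a_i, step_enab[[ii]]))) == 0) {
            all_disturb <- FALSE
            break
          }
        }
        if (all_disturb) n_bad <- n_bad + 1L
      }
      if (n_bad > 1L) return(fail("independence condition violated"))
    }
  }
  TRUE
}

#' Export an under-approximation witness
#'
#' @param w An `an_ua_witness`.
#' @param file Optional path for the DOT output.
#' @return For `ua_witness_dot`, DOT source; for `ua_witness_json`, a JSON
#'   record of the chosen context and paths.
#' @export
ua_witness_dot <- function(w, file = NULL) {
  nodes <- unique(c(w$edges$from, w$edges$to))
  shape <- function(v) {
    if (grepl("#", v, fixed = TRUE)) "circle" else
      if (grepl("~>", v, fixed = TRUE)) "plaintext" else "box"
  }
  lines <- c("digraph ua_witness {")
  for (i in seq_along(nodes)) {
    lines <- c(lines, sprintf('  n%d [shape=%s, label="%s"];', i,
                              shape(nodes[i]),
                              gsub('"', '\\\\"', nodes[i])))
  }
  for (r in seq_len(nrow(w$edges))) {
    lines <- c(lines, sprintf("  n%d -> n%d;",
                              match(w$edges$from[r], nodes),
                              match(w$edges$to[r], nodes)))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname ua_witness_dot
#' @export
ua_witness_json <- function(w, file = NULL) {
  obj <- list(
    targets = as.list(w$targets),
    context_choice = as.list(w$context_choice),
    chosen_paths = w$chosen_paths,
    local_states = w$local_states
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
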
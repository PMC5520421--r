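# Independent brute-force oracles. These deliberately share no code with the
# package internals they check: transition applicability is re-derived from
# the transitions tibble, the state space is enumerated depth-first (the
# package uses breadth-first), strong connectivity uses a mutual-reachability
# closure (the package uses igraph), and the CTL characterization of
# bifurcations is evaluated directly on the full graph.

oracle_enabled_rows <- function(net, s) {
  tr <- net$transitions
  which(vapply(seq_len(nrow(tr)), function(r) {
    if (s[[tr$automaton[r]]] != tr$origin[r]) return(FALSE)
    cond <- tr$condition[[r]]
    for (b in names(cond)) if (s[[b]] != cond[[b]]) return(FALSE)
    TRUE
  }, logical(1)))
}

oracle_apply_row <- function(net, s, r) {
  s[[net$transitions$automaton[r]]] <- net$transitions$dest[r]
  s
}

# depth-first enumeration of the reachable set; returns list(states, keys,
# edges) with edges rows (from key, transition id, to key)
oracle_enumerate <- function(net, s0, cap = 20000) {
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  states <- list()
  edges <- list()
  stack <- list(s0)
  assign(format_an_state(s0), TRUE, envir = seen)
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    states[[length(states) + 1L]] <- s
    if (length(states) > cap) stop("oracle cap exceeded")
    for (r in oracle_enabled_rows(net, s)) {
      s2 <- oracle_apply_row(net, s, r)
      k2 <- format_an_state(s2)
      edges[[length(edges) + 1L]] <- c(format_an_state(s),
                                       net$transitions$id[r], k2)
      if (is.null(seen[[k2]])) {
        assign(k2, TRUE, envir = seen)
        stack[[length(stack) + 1L]] <- s2
      }
    }
  }
  keys <- vapply(states, format_an_state, character(1))
  list(states = states, keys = keys,
       edges = if (length(edges)) do.call(rbind, edges) else
         matrix(character(0), ncol = 3))
}

# truth of "some state containing goal is reachable from s", per reachable
# state of `enum`; computed by iterating "has a successor with the verdict"
# to a fixed point (no shared code with the package's backward BFS)
oracle_goal_verdicts <- function(net, enum, goal) {
  verdict <- vapply(enum$states, function(s) s[[goal$automaton]] == goal$index,
                    logical(1))
  names(verdict) <- enum$keys
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(enum$edges))) {
      from <- enum$edges[r, 1]; to <- enum$edges[r, 3]
      if (!verdict[[from]] && verdict[[to]]) {
        verdict[[from]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  verdict
}

oracle_reach <- function(net, s, goal, cap = 20000) {
  enum <- oracle_enumerate(net, s, cap = cap)
  any(vapply(enum$states, function(x) x[[goal$automaton]] == goal$index,
             logical(1)))
}

# direct evaluation of the CTL characterization of bifurcation transitions:
# a transition t is a bifurcation iff some reachable state s has t enabled,
# the goal reachable from s, and the goal unreachable from s.t
oracle_ctl_bifurcations <- function(net, s0, goal, cap = 20000) {
  enum <- oracle_enumerate(net, s0, cap = cap)
  verdict <- oracle_goal_verdicts(net, enum, goal)
  hits <- character(0)
  for (s in enum$states) {
    if (!verdict[[format_an_state(s)]]) next
    for (r in oracle_enabled_rows(net, s)) {
      s2 <- oracle_apply_row(net, s, r)
      if (!verdict[[format_an_state(s2)]]) {
        hits <- c(hits, net$transitions$id[r])
      }
    }
  }
  unique(hits)[order(match(unique(hits), net$transitions$id))]
}

# terminal SCCs by mutual-reachability closure over the enumerated graph
oracle_attractors <- function(net, s0, cap = 5000) {
  enum <- oracle_enumerate(net, s0, cap = cap)
  n <- length(enum$keys)
  idx <- stats::setNames(seq_len(n), enum$keys)
  reach <- diag(n) > 0
  if (nrow(enum$edges)) {
    for (r in seq_len(nrow(enum$edges))) {
      reach[idx[[enum$edges[r, 1]]], idx[[enum$edges[r, 3]]]] <- TRUE
    }
  }
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    comp[which(reach[i, ] & reach[, i])] <- nc
  }
  terminal <- vapply(seq_len(nc), function(cc) {
    members <- which(comp == cc)
    all(comp[apply(reach[members, , drop = FALSE], 2, any)] == cc)
  }, logical(1))
  lapply(which(terminal), function(cc) {
    sort(enum$keys[comp == cc], method = "radix")
  })
}

# exhaustive enumeration of local paths straight from the definition: all
# transition tuples of the automaton up to length k-1, filtered on chaining
# and non-revisiting
oracle_local_paths <- function(net, automaton, from, to) {
  if (from == to) return(list(character(0)))
  tr <- net$transitions[net$transitions$automaton == automaton, ]
  k <- length(net$automata[[automaton]])
  found <- list()
  if (nrow(tr) == 0) return(found)
  for (len in 1:max(1, k - 1)) {
    tuples <- expand.grid(rep(list(seq_len(nrow(tr))), len))
    for (r in seq_len(nrow(tuples))) {
      rows <- as.integer(tuples[r, ])
      ok <- tr$origin[rows[1]] == from && tr$dest[rows[len]] == to
      if (ok && len > 1) {
        for (nn in 2:len) {
          if (tr$origin[rows[nn]] != tr$dest[rows[nn - 1]]) { ok <- FALSE; break }
        }
      }
      if (ok) {
        for (nn in seq_len(len)) {
          for (mm in seq_len(nn - 1)) {
            if (tr$dest[rows[nn]] == tr$origin[rows[mm]]) { ok <- FALSE; break }
          }
          if (!ok) break
        }
      }
      if (ok) found[[length(found) + 1L]] <- tr$id[rows]
    }
  }
  found
}

# full tripartite graph straight from the definition (all ordered pairs)
oracle_lcg_counts <- function(net) {
  n_ls <- sum(lengths(net$automata))
  n_obj <- 0L; n_paths <- 0L; n_edges <- 0L
  for (a in names(net$automata)) {
    for (i in net$automata[[a]]) {
      for (j in net$automata[[a]]) {
        n_obj <- n_obj + 1L
        paths <- oracle_local_paths(net, a, i, j)
        n_paths <- n_paths + length(paths)
        n_edges <- n_edges + 1L          # a_j -> objective
        n_edges <- n_edges + length(paths)  # objective -> paths
        for (p in paths) {
          enab <- integer(0)
          seen <- character(0)
          for (tid in p) {
            cond <- net$transitions$condition[[match(tid, net$transitions$id)]]
            for (b in names(cond)) {
              key <- paste0(b, "=", cond[[b]])
              if (!(key %in% seen)) seen <- c(seen, key)
            }
          }
          n_edges <- n_edges + length(seen)  # path -> condition states
        }
      }
    }
  }
  list(local_states = n_ls, objectives = n_obj, paths = n_paths,
       edges = n_edges)
}

# direct fixpoint of the necessary-condition operator over the FULL
# objective set (the package iterates only over a lazily collected subset)
oracle_oa <- function(net, s, goal) {
  objs <- list()
  for (a in names(net$automata)) {
    for (j in net$automata[[a]]) {
      objs[[paste0(a, ">", j)]] <- list(a = a, j = j,
        paths = oracle_local_paths(net, a, s[[a]], j))
    }
  }
  omega <- character(0)
  repeat {
    added <- FALSE
    for (key in names(objs)) {
      if (key %in% omega) next
      for (p in objs[[key]]$paths) {
        ok <- TRUE
        for (tid in p) {
          cond <- net$transitions$condition[[match(tid, net$transitions$id)]]
          for (b in names(cond)) {
            if (!(paste0(b, ">", cond[[b]]) %in% omega)) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) { omega <- c(omega, key); added <- TRUE; break }
      }
    }
    if (!added) break
  }
  paste0(goal$automaton, ">", goal$index) %in% omega
}

# asynchronous successor states of a Boolean-network state, straight from
# the update functions evaluated as R expressions
oracle_bn_successors <- function(exprs, s) {
  env <- as.list(s == 1L)
  out <- list()
  for (x in names(exprs)) {
    v <- as.integer(eval(exprs[[x]], envir = env))
    if (v != s[[x]]) {
      s2 <- s
      s2[[x]] <- v
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

oracle_bn_exprs <- function(rows) {
  exprs <- list()
  for (row in rows) {
    comma <- regexpr(",", row, fixed = TRUE)
    node <- trimws(substr(row, 1, comma - 1))
    exprs[[node]] <- parse(text = trimws(substr(row, comma + 1,
                                                nchar(row))))[[1]]
  }
  exprs
}
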
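#' Explicit reachable state graph
#'
#' Breadth-first closure of an initial global state under the asynchronous
#' semantics: states are explored in insertion order and, within a state,
#' transitions in id order, so the construction is deterministic.
#'
#' @param net An `an` object.
#' @param s0 Initial global state (see [an_state()]). Defaults to the
#'   network's declared initial state.
#' @param state_cap Maximum number of states to enumerate before raising an
#'   error of class `an_state_cap` (signals that the model needs the
#'   approximate pipeline). Default 1e6.
#' @return An object of class `an_state_graph`: list with `states` (list of
#'   named integer vectors; element 1 is `s0`), `keys` (canonical strings),
#'   `edges` (tibble with columns `from`, `to` (state indices) and
#'   `transition` (id)), and `net`.
#' @examples
#' fx <- an_builtin("fig1")
#' g <- reachable_graph(fx$net, fx$initial)
#' length(g$states)
#' @export
reachable_graph <- function(net, s0 = net$initial, state_cap = 1e6) {
  stopifnot(inherits(net, "an"))
  s0 <- an_state(net, s0)
  comp <- an_compile(net)
  ids <- map_chr(comp$trans, "id")

  index <- new.env(parent = emptyenv(), hash = TRUE)
  states <- vector("list", 256L)
  n <- 1L
  states[[1L]] <- unname(s0)
  assign(state_key(unname(s0)), 1L, envir = index)

  e_from <- integer(0); e_to <- integer(0); e_tr <- integer(0)
  head <- 1L
  while (head <= n) {
    s <- states[[head]]
    for (k in enabled_idx(comp, s)) {
      t <- comp$trans[[k]]
      s2 <- s
      s2[[t$a]] <- t$j
      key <- state_key(s2)
      to <- index[[key]]
      if (is.null(to)) {
        if (n >= state_cap) {
          an_error(paste0("state cap exceeded (", state_cap, " states)"),
                   "an_state_cap")
        }
        n <- n + 1L
        if (n > length(states)) states <- c(states, vector("list", n))
        states[[n]] <- s2
        assign(key, n, envir = index)
        to <- n
      }
      e_from <- c(e_from, head); e_to <- c(e_to, to); e_tr <- c(e_tr, k)
    }
    head <- head + 1L
  }
  states <- states[seq_len(n)]
  states <- lapply(states, function(s) stats::setNames(s, comp$autos))
  structure(
    list(
      states = states,
      keys = map_chr(states, format_an_state),
      edges = tibble(from = e_from, to = e_to, transition = ids[e_tr]),
      net = net
    ),
    class = "an_state_graph"
  )
}

#' @export
print.an_state_graph <- function(x, ...) {
  cat("Reachable state graph:", length(x$states), "states,",
      nrow(x$edges), "transitions\n")
  cat("root:", x$keys[1], "\n")
  invisible(x)
}

#' @rdname reachable_graph
#' @param x An `an_state_graph`.
#' @param ... Unused.
#' @return `tidy()` returns the edge list as a tibble with the source and
#'   target states in canonical string form.
#' @export
tidy.an_state_graph <- function(x, ...) {
  tibble(
    from = x$keys[x$edges$from],
    transition = x$edges$transition,
    to = x$keys[x$edges$to]
  )
}

#' @rdname reachable_graph
#' @export
glance.an_state_graph <- function(x, ...) {
  att <- attractors(x)
  tibble(
    n_states = length(x$states),
    n_edges = nrow(x$edges),
    n_attractors = nrow(att),
    root = x$keys[1]
  )
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = g$edges$from, to = g$edges$to),
    directed = TRUE,
    vertices = data.frame(name = seq_along(g$states))
  )
}

#' Attractors of a reachable state graph
#'
#' An attractor is a set of global states that is strongly connected and
#' terminal under reachability: once inside, the dynamics can never leave.
#' Attractors are the terminal strongly connected components of the state
#' graph and model the long-run behaviours of the network.
#'
#' @param g An `an_state_graph` from [reachable_graph()].
#' @return A tibble with one row per attractor, ordered by the canonical
#'   minimal state string: columns `attractor` (integer id), `size`, and
#'   `states` (list column; each element a character vector of canonical
#'   state strings). Attribute `membership` maps state indices to attractor
#'   id (`NA` for transient states).
#' @examples
#' fx <- an_builtin("fig1")
#' attractors(reachable_graph(fx$net, fx$initial))
#' @export
attractors <- function(g) {
  stopifnot(inherits(g, "an_state_graph"))
  n <- length(g$states)
  if (nrow(g$edges) == 0) {
    out <- tibble(attractor = 1L, size = 1L, states = list(g$keys[1]))
    attr(out, "membership") <- 1L
    return(out)
  }
  ig <- as_igraph(g)
  scc <- igraph::components(ig, mode = "strong")
  memb <- scc$membership
  # terminal SCCs: no edge leaves the component
  leaving <- unique(memb[g$edges$from][memb[g$edges$from] !=
                                         memb[g$edges$to]])
  terminal <- setdiff(seq_len(scc$no), leaving)

  sets <- lapply(terminal, function(cc) sort(g$keys[which(memb == cc)],
                                             method = "radix"))
  ord <- order(map_chr(sets, 1), method = "radix")
  sets <- sets[ord]
  terminal <- terminal[ord]

  membership <- rep(NA_integer_, n)
  for (i in seq_along(terminal)) {
    membership[memb == terminal[i]] <- i
  }
  out <- tibble(
    attractor = seq_along(sets),
    size = map_int(sets, length),
    states = sets
  )
  attr(out, "membership") <- membership
  out
}

goal_mask <- function(g, goal) {
  goal <- check_goal(g$net, goal)
  map_lgl(g$states, function(s) s[[goal$automaton]] == goal$index)
}

# logical vector over g$states: can reach a goal-containing state within g
goal_connected_mask <- function(g, goal) {
  inset <- goal_mask(g, goal)
  if (!any(inset)) return(inset)
  n <- length(g$states)
  # backward closure over reversed edges
  preds <- split(g$edges$from, g$edges$to)
  conn <- inset
  queue <- which(inset)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (p in preds[[as.character(v)]]) {
      if (!conn[[p]]) {
        conn[[p]] <- TRUE
        queue <- c(queue, p)
      }
    }
  }
  conn
}

#' States connected to the goal
#'
#' The subset of the reachable state graph from which some state containing
#' the goal local state is still reachable (computed by backward closure from
#' the goal-containing states; the relation is reflexive, so goal-containing
#' states are themselves connected).
#'
#' @param g An `an_state_graph`.
#' @param goal An [an_goal()] (or string `"a=2"`).
#' @return A tibble with columns `state` (canonical string), `index` (state
#'   index in `g`) and `contains_goal`.
#' @examples
#' fx <- an_builtin("fig1")
#' g <- reachable_graph(fx$net, fx$initial)
#' nrow(goal_connected(g, fx$goal))
#' @export
goal_connected <- function(g, goal) {
  stopifnot(inherits(g, "an_state_graph"))
  conn <- goal_connected_mask(g, goal)
  idx <- which(conn)
  tibble(
    state = g$keys[idx],
    index = idx,
    contains_goal = goal_mask(g, goal)[idx]
  )
}

#' Exact bifurcation transitions (explicit-state oracle)
#'
#' A bifurcation transition is a local transition `t_b` with a reachable
#' witness state `s_b` such that the goal is reachable from `s_b` but not
#' from `s_u = s_b . t_b`. On the explicit reachable state graph these are
#' exactly the local transitions labelling an edge from a goal-connected
#' state to a non-goal-connected state; this evaluation is sound and
#' complete.
#'
#' @param net An `an` object.
#' @param s0 Initial global state.
#' @param goal An [an_goal()] (or string).
#' @param state_cap Passed to [reachable_graph()].
#' @param witnesses Attach all crossing state pairs per transition
#'   (default `TRUE`); set `FALSE` to suppress on large graphs.
#' @return An `an_bifurcations` tibble: one row per bifurcation transition
#'   with columns `transition`, `automaton`, `origin`, `dest`, `condition`,
#'   `method` (`"exact"`) and `witnesses` (list column of tibbles with
#'   canonical `s_b`, `s_u` strings).
#' @examples
#' fx <- an_builtin("fig1")
#' exact_bifurcations(fx$net, fx$initial, fx$goal)$transition
#' @export
exact_bifurcations <- function(net, s0 = net$initial, goal, state_cap = 1e6,
                               witnesses = TRUE) {
  g <- reachable_graph(net, s0, state_cap = state_cap)
  conn <- goal_connected_mask(g, goal)
  crossing <- g$edges[conn[g$edges$from] & !conn[g$edges$to], ]
  tids <- unique(crossing$transition)
  tids <- tids[order(match(tids, net$transitions$id))]
  rows <- lapply(tids, function(tid) {
    tr <- net$transitions[net$transitions$id == tid, ]
    w <- if (witnesses) {
      sub <- crossing[crossing$transition == tid, ]
      tibble(s_b = g$keys[sub$from], s_u = g$keys[sub$to])
    } else {
      tibble(s_b = character(0), s_u = character(0))
    }
    tibble(
      transition = tid, automaton = tr$automaton, origin = tr$origin,
      dest = tr$dest, condition = tr$condition, method = "exact",
      witnesses = list(w)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      transition = character(0), automaton = character(0),
      origin = integer(0), dest = integer(0), condition = list(),
      method = character(0), witnesses = list()
    )
  }
  class(out) <- c("an_bifurcations", class(out))
  out
}

#' Export a state graph as JSON or DOT
#'
#' @param g An `an_state_graph`.
#' @param file Optional output path.
#' @return The JSON string / DOT source (invisibly when written to `file`).
#' @export
state_graph_json <- function(g, file = NULL) {
  obj <- list(
    root = g$keys[1],
    states = g$keys,
    edges = data.frame(
      from = g$keys[g$edges$from],
      transition = g$edges$transition,
      to = g$keys[g$edges$to],
      stringsAsFactors = FALSE
    )
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname state_graph_json
#' @export
state_graph_dot <- function(g, file = NULL) {
  lines <- c("digraph states {", "  node [shape=box];")
  for (i in seq_along(g$keys)) {
    lines <- c(lines, sprintf('  s%d [label="%s"];', i, g$keys[i]))
  }
  for (r in seq_len(nrow(g$edges))) {
    lines <- c(lines, sprintf('  s%d -> s%d [label="%s"];',
                              g$edges$from[r], g$edges$to[r],
                              g$edges$transition[r]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(txt))
  }
  txt
}

#' Plot a reachable state graph
#'
#' Mirrors the transition-graph view used when reading off bifurcations by
#' eye: states still connected to the goal are shaded, goal-containing states
#' outlined, and edges crossing out of the goal-connected set (the
#' bifurcations) drawn in red.
#'
#' @param object An `an_state_graph`.
#' @param goal Optional [an_goal()]; enables the goal-connected shading.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.an_state_graph <- function(object, goal = NULL, ...) {
  g <- object
  ig <- as_igraph(g)
  # fixed layout seed, restoring the caller's RNG state
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(1L)
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble(
    index = seq_along(g$states), x = xy[, 1], y = xy[, 2], label = g$keys
  )
  if (!is.null(goal)) {
    conn <- goal_connected_mask(g, goal)
    nodes$status <- ifelse(goal_mask(g, goal), "goal",
                           ifelse(conn, "goal-connected", "goal-lost"))
  } else {
    nodes$status <- "state"
  }
  edges <- tibble(
    x = nodes$x[g$edges$from], y = nodes$y[g$edges$from],
    xend = nodes$x[g$edges$to], yend = nodes$y[g$edges$to],
    bifurcation = if (!is.null(goal)) {
      conn[g$edges$from] & !conn[g$edges$to]
    } else {
      FALSE
    }
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$bifurcation),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 0.4
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "red"), guide = "none"
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   fill = .data$status),
      size = 2.6
    ) +
    ggplot2::scale_fill_manual(values = c(
      "goal" = "#9ecae1", "goal-connected" = "grey85",
      "goal-lost" = "white", "state" = "grey92"
    )) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' @rdname autoplot.an_state_graph
#' @export
plot_state_graph <- function(object, goal = NULL, ...) {
  autoplot.an_state_graph(object, goal = goal, ...)
}
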
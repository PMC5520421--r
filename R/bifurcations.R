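#' Approximate identification of bifurcation transitions
#'
#' Enumerates candidate triples `(t_b, s_b, s_u)` per local transition and
#' accepts a transition as a bifurcation when some assignment of the free
#' automata satisfies the relaxed conditions:
#' \itemize{
#'   \item the over-approximation refutes goal reachability from
#'     `s_u = s_b . t_b` (and `s_u` does not itself contain the goal);
#'   \item the under-approximation certifies goal reachability from `s_b`;
#'   \item `s_b` is certified reachable from `s0`: in mode `"I3"` by
#'     membership in the explicitly computed reachable state set, in mode
#'     `"I3sharp"` by an under-approximation witness for the simultaneous
#'     reachability of all coordinates of `s_b` from `s0`.
#' }
#' The combination is sound — every reported transition is a true
#' bifurcation transition — but incomplete (false negatives are possible;
#' mode `"I3sharp"` trades more false negatives for scalability, as it never
#' builds the state space). Candidates are explored fail-fast: the cheap
#' over-approximation fixpoint prunes an assignment before any
#' under-approximation search is attempted.
#'
#' @param net An `an` object.
#' @param s0 Initial global state.
#' @param goal An [an_goal()] (or string `"a=2"`).
#' @param mode `"I3"` (explicit reachable set, fewer false negatives) or
#'   `"I3sharp"` (fully static, scalable).
#' @param state_cap Passed to [reachable_graph()] in mode `"I3"`.
#' @param all_witnesses Keep every accepted `(s_b, s_u)` pair per transition
#'   instead of the first.
#' @return An `an_bifurcations` tibble (same shape as
#'   [exact_bifurcations()]), `method` column set to the mode.
#' @examples
#' fx <- an_builtin("fig1")
#' find_bifurcations(fx$net, fx$initial, fx$goal, mode = "I3")$transition
#' @export
find_bifurcations <- function(net, s0 = net$initial, goal,
                              mode = c("I3", "I3sharp"), state_cap = 1e6,
                              all_witnesses = FALSE) {
  stopifnot(inherits(net, "an"))
  mode <- match.arg(mode)
  s0 <- an_state(net, s0)
  goal <- check_goal(net, goal)
  cache <- lp_cache(net)

  reach_keys <- NULL
  if (mode == "I3") {
    g <- reachable_graph(net, s0, state_cap = state_cap)
    reach_keys <- new.env(parent = emptyenv(), hash = TRUE)
    for (k in g$keys) assign(k, TRUE, envir = reach_keys)
  }

  autos <- names(net$automata)
  goal_target <- stats::setNames(goal$index, goal$automaton)
  rows <- list()

  for (r in seq_len(nrow(net$transitions))) {
    tr <- net$transitions[r, ]
    a <- tr$automaton
    cond <- tr$condition[[1]]

    # s_u is forced at the transition's automaton (dest) and its condition
    fixed <- c(stats::setNames(tr$dest, a), cond)
    # guard: s_u must not already contain the goal
    if (goal$automaton %in% names(fixed) &&
        fixed[[goal$automaton]] == goal$index) next

    free <- setdiff(autos, names(fixed))
    domains <- lapply(free, function(b) {
      d <- net$automata[[b]]
      if (b == goal$automaton) d <- setdiff(d, goal$index)
      d
    })
    if (any(lengths(domains) == 0)) next

    assignments <- if (length(free)) {
      grid <- expand.grid(rev(domains), KEEP.OUT.ATTRS = FALSE)
      grid <- grid[, rev(seq_along(free)), drop = FALSE]
      colnames(grid) <- free
      grid
    } else {
      as.data.frame(matrix(integer(0), nrow = 1, ncol = 0))
    }

    wits <- list()
    for (ai in seq_len(nrow(assignments))) {
      s_u <- stats::setNames(integer(length(autos)), autos)
      s_u[names(fixed)] <- fixed
      for (b in free) s_u[[b]] <- assignments[[b]][ai]
      s_u <- s_u[autos]

      # (I1#) the goal must be refuted from s_u
      if (oa_reach(net, s_u, goal, cache = cache)$decision) next

      s_b <- s_u
      s_b[[a]] <- tr$origin

      # reachability of s_b from s0
      if (mode == "I3") {
        if (is.null(reach_keys[[format_an_state(s_b)]])) next
      } else {
        wb <- ua_reach(net, an_context(net, s0), targets = s_b,
                       cache = cache)
        if (is.null(wb)) next
      }

      # (I2#) the goal must be certified reachable from s_b
      w <- ua_reach(net, an_context(net, s_b), targets = goal_target,
                    cache = cache)
      if (is.null(w)) next

      wits[[length(wits) + 1L]] <- list(s_b = format_an_state(s_b),
                                        s_u = format_an_state(s_u))
      if (!all_witnesses) break
    }

    if (length(wits)) {
      rows[[length(rows) + 1L]] <- tibble(
        transition = tr$id, automaton = a, origin = tr$origin,
        dest = tr$dest, condition = tr$condition, method = mode,
        witnesses = list(tibble(
          s_b = map_chr(wits, "s_b"), s_u = map_chr(wits, "s_u")
        ))
      )
    }
  }

  out <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble(
      transition = character(0), automaton = character(0),
      origin = integer(0), dest = integer(0), condition = list(),
      method = character(0), witnesses = list()
    )
  }
  class(out) <- c("an_bifurcations", class(out))
  out
}

#' @export
print.an_bifurcations <- function(x, ...) {
  cat("Bifurcation transitions:", nrow(x), "\n")
  NextMethod()
}

#' @rdname find_bifurcations
#' @param x An `an_bifurcations` tibble.
#' @param ... Unused.
#' @return `tidy()` flattens the witnesses: one row per (transition, witness
#'   pair); `glance()` gives per-method counts.
#' @export
tidy.an_bifurcations <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(transition = character(0), method = character(0),
                  s_b = character(0), s_u = character(0)))
  }
  out <- lapply(seq_len(nrow(x)), function(r) {
    w <- x$witnesses[[r]]
    if (nrow(w) == 0) w <- tibble(s_b = NA_character_, s_u = NA_character_)
    tibble(transition = x$transition[r], method = x$method[r],
           s_b = w$s_b, s_u = w$s_u)
  })
  dplyr::bind_rows(out)
}

#' @rdname find_bifurcations
#' @export
glance.an_bifurcations <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(method = character(0), n_transitions = integer(0),
                  n_witnesses = integer(0)))
  }
  as_tibble(as.data.frame(x)) |>
    group_by(.data$method) |>
    summarise(
      n_transitions = dplyr::n(),
      n_witnesses = sum(map_int(.data$witnesses, nrow))
    )
}

#' Export bifurcation results
#'
#' @param x An `an_bifurcations` tibble.
#' @param file Optional output path.
#' @return `bifurcations_json()` returns records with the transition
#'   definition, method and witnesses; `bifurcations_tsv()` a human-readable
#'   table.
#' @export
bifurcations_json <- function(x, file = NULL) {
  recs <- lapply(seq_len(nrow(x)), function(r) {
    cond <- x$condition[[r]]
    list(
      transition = x$transition[r],
      automaton = x$automaton[r],
      origin = x$origin[r],
      dest = x$dest[r],
      condition = if (length(cond)) as.list(cond) else
        stats::setNames(list(), character(0)),
      method = x$method[r],
      witnesses = x$witnesses[[r]]
    )
  })
  txt <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname bifurcations_json
#' @export
bifurcations_tsv <- function(x, file = NULL) {
  df <- data.frame(
    transition = x$transition,
    automaton = x$automaton,
    origin = x$origin,
    dest = x$dest,
    condition = map_chr(x$condition, function(cond) {
      if (length(cond)) paste0(names(cond), "=", cond, collapse = ",") else ""
    }),
    method = x$method,
    n_witnesses = map_int(x$witnesses, nrow),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Compare bifurcation identification methods on one instance
#'
#' Runs the exact explicit-state oracle (when the state space fits under
#' `state_cap`) and both approximate modes on the same instance and reports
#' the per-method transition sets, their differences from exact, and wall
#' times.
#'
#' @inheritParams find_bifurcations
#' @return An object of class `an_mode_report`: a tibble with one row per
#'   method (`method`, `n`, `transitions` list column, `missed` list column
#'   of exact-only ids, `seconds`).
#' @examples
#' fx <- an_builtin("fig1")
#' classify_modes(fx$net, fx$initial, fx$goal)
#' @export
classify_modes <- function(net, s0 = net$initial, goal, state_cap = 1e6) {
  goal <- check_goal(net, goal)
  timed <- function(fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), an_state_cap = function(e) NULL)
    list(res = res, seconds = proc.time()[["elapsed"]] - t0)
  }
  ex <- timed(function() exact_bifurcations(net, s0, goal,
                                            state_cap = state_cap))
  i3 <- timed(function() find_bifurcations(net, s0, goal, mode = "I3",
                                           state_cap = state_cap))
  i3s <- timed(function() find_bifurcations(net, s0, goal, mode = "I3sharp"))

  exact_ids <- if (!is.null(ex$res)) ex$res$transition else NULL
  row <- function(name, tm) {
    ids <- if (!is.null(tm$res)) tm$res$transition else character(0)
    tibble(
      method = name,
      n = if (is.null(tm$res)) NA_integer_ else length(ids),
      transitions = list(ids),
      missed = list(if (is.null(exact_ids)) character(0) else
        setdiff(exact_ids, ids)),
      seconds = tm$seconds
    )
  }
  out <- dplyr::bind_rows(
    row("exact", ex), row("I3", i3), row("I3sharp", i3s)
  )
  class(out) <- c("an_mode_report", class(out))
  out
}
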
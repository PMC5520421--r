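#' Objectives
#'
#' An objective `a_i ~> a_j` is the task of driving automaton `a` from local
#' state `i` to local state `j`. Objectives are the pivot of the static
#' reachability analysis: reaching a local state decomposes into realizing an
#' acyclic within-automaton path, whose conditions spawn further objectives.
#'
#' @param automaton Automaton identifier.
#' @param from,to Local-state indices.
#' @return An object of class `an_objective`.
#' @examples
#' an_objective("a", 0, 2)
#' @export
an_objective <- function(automaton, from, to) {
  structure(
    list(automaton = automaton, from = as.integer(from), to = as.integer(to)),
    class = "an_objective"
  )
}

#' @export
print.an_objective <- function(x, ...) {
  cat("Objective ", obj_key(x), "\n", sep = "")
  invisible(x)
}

obj_key <- function(obj) paste0(obj$automaton, ":", obj$from, "~>", obj$to)
ls_key <- function(automaton, index) paste0(automaton, "=", index)

check_objective <- function(net, obj) {
  stopifnot(inherits(obj, "an_objective"))
  a <- obj$automaton
  if (!a %in% names(net$automata) || !(obj$from %in% net$automata[[a]]) ||
      !(obj$to %in% net$automata[[a]])) {
    an_error(paste0("objective references undeclared local states: ",
                    obj_key(obj)), "an_semantic_error")
  }
  obj
}

#' Local paths of an objective
#'
#' The local paths of `a_i ~> a_j` are the acyclic sequences of transitions
#' of automaton `a` chaining from `i` to `j`: consecutive steps chain
#' (`dest(step n) = orig(step n+1)`) and no step's destination revisits an
#' earlier step's origin. For `i = j` the set is the singleton empty path.
#' Enumeration is a depth-first search pruning revisited origins; the result
#' order is deterministic (lexicographic in step ids, shorter prefixes
#' first).
#'
#' @param net An `an` object.
#' @param obj An [an_objective()].
#' @return A list of local paths; each path is a character vector of
#'   transition ids (the empty path is `character(0)`).
#' @examples
#' fx <- an_builtin("fig1")
#' local_paths(fx$net, an_objective("c", 0, 2))
#' @export
local_paths <- function(net, obj) {
  stopifnot(inherits(net, "an"))
  check_objective(net, obj)
  if (obj$from == obj$to) return(list(character(0)))
  tr <- net$transitions[net$transitions$automaton == obj$automaton, ]
  paths <- list()
  # DFS over simple paths in the local-state graph of automaton `obj$automaton`
  recurse <- function(current, visited_origins, steps) {
    rows <- which(tr$origin == current)
    for (r in rows) {
      d <- tr$dest[r]
      if (d %in% visited_origins) next
      steps2 <- c(steps, tr$id[r])
      if (d == obj$to) {
        paths[[length(paths) + 1L]] <<- steps2
      } else {
        recurse(d, c(visited_origins, current), steps2)
      }
    }
  }
  recurse(obj$from, integer(0), character(0))
  paths
}

#' Union of the conditions along a local path
#'
#' @param net An `an` object.
#' @param path A local path (character vector of transition ids, as returned
#'   by [local_paths()]).
#' @return A named integer vector: the union of the enabling conditions of
#'   the path's steps, sorted by automaton then index. Since different steps
#'   may require different local states of the same automaton, a name can
#'   occur more than once; the empty path has an empty union.
#' @examples
#' fx <- an_builtin("fig1")
#' p <- local_paths(fx$net, an_objective("c", 0, 2))[[1]]
#' enab_of_path(fx$net, p)
#' @export
enab_of_path <- function(net, path) {
  if (length(path) == 0) return(stats::setNames(integer(0), character(0)))
  rows <- match(path, net$transitions$id)
  if (anyNA(rows)) an_error("unknown transition id in path",
                            "an_semantic_error")
  conds <- net$transitions$condition[rows]
  out <- integer(0)
  for (cond in conds) {
    for (b in names(cond)) {
      k <- cond[[b]]
      if (!any(names(out) == b & out == k)) {
        out <- c(out, stats::setNames(k, b))
      }
    }
  }
  if (length(out) == 0) return(stats::setNames(integer(0), character(0)))
  out[order(names(out), out, method = "radix")]
}

# memoized local-paths lookup used by the static analyses
lp_cache <- function(net) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  env$net <- net
  env
}

cached_local_paths <- function(cache, automaton, from, to) {
  key <- paste0(automaton, ":", from, ">", to)
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  paths <- local_paths(cache$net, an_objective(automaton, from, to))
  # pair each path with its enab once
  val <- lapply(paths, function(p) {
    list(steps = p, enab = enab_of_path(cache$net, p),
         step_enabs = lapply(p, function(tid) {
           net <- cache$net
           net$transitions$condition[[match(tid, net$transitions$id)]]
         }))
  })
  assign(key, val, envir = cache)
  val
}

#' Build a Local Causality Graph
#'
#' The Local Causality Graph (LCG) is the tripartite digraph over local
#' states, objectives and local paths with exactly three edge families:
#' from each local state `a_j` to every objective `a_i ~> a_j` ending at it;
#' from each objective to each of its local paths; and from each local path
#' to every local state of its condition union. It abstracts all executions
#' of the network and is the substrate of both reachability approximations.
#'
#' By default the graph is built lazily, restricted to the nodes reachable
#' (following edge direction) from the target local states of the given root
#' objectives; with `full = TRUE` the complete graph over all objectives is
#' produced.
#'
#' @param net An `an` object.
#' @param roots List of [an_objective()] roots (ignored when `full = TRUE`).
#' @param full Build the LCG over all ordered local-state pairs.
#' @return An object of class `an_lcg`: list with `local_states` (tibble
#'   `automaton`, `index`), `objectives` (tibble `automaton`, `from`, `to`),
#'   `paths` (tibble `objective`, `path_id`, `steps` list column), and
#'   `edges` (tibble `from`, `to` over node keys; local-state keys are
#'   `"a=0"`, objective keys `"a:0~>2"`, path keys `"a:0~>2#1"`).
#' @examples
#' fx <- an_builtin("fig1")
#' lcg <- build_lcg(fx$net, list(an_objective("a", 0, 2)))
#' nrow(lcg$edges)
#' @export
build_lcg <- function(net, roots = list(), full = FALSE) {
  stopifnot(inherits(net, "an"))
  cache <- lp_cache(net)

  if (full) {
    roots <- list()
    for (a in names(net$automata)) {
      for (i in net$automata[[a]]) {
        for (j in net$automata[[a]]) {
          roots[[length(roots) + 1L]] <- an_objective(a, i, j)
        }
      }
    }
  } else {
    roots <- lapply(roots, check_objective, net = net)
  }

  ls_seen <- new.env(parent = emptyenv())
  obj_seen <- new.env(parent = emptyenv())
  edges_from <- character(0); edges_to <- character(0)
  ls_rows <- list(); obj_rows <- list(); path_rows <- list()

  add_edge <- function(from, to) {
    edges_from <<- c(edges_from, from)
    edges_to <<- c(edges_to, to)
  }

  visit_obj <- function(a, i, j) {
    ok <- paste0(a, ":", i, "~>", j)
    if (!is.null(obj_seen[[ok]])) return(invisible(NULL))
    assign(ok, TRUE, envir = obj_seen)
    obj_rows[[length(obj_rows) + 1L]] <<- list(automaton = a, from = i, to = j)
    okey <- obj_node_key(a, i, j)
    paths <- cached_local_paths(cache, a, i, j)
    for (pi in seq_along(paths)) {
      pkey <- paste0(okey, "#", pi)
      path_rows[[length(path_rows) + 1L]] <<-
        list(objective = okey, path_id = pkey, steps = paths[[pi]]$steps)
      add_edge(okey, pkey)
      enab <- paths[[pi]]$enab
      for (ii in seq_along(enab)) {
        visit_ls(names(enab)[ii], enab[[ii]])
        add_edge(pkey, ls_key(names(enab)[ii], enab[[ii]]))
      }
    }
    invisible(NULL)
  }

  visit_ls <- function(a, j) {
    lk <- ls_key(a, j)
    if (!is.null(ls_seen[[lk]])) return(invisible(NULL))
    assign(lk, TRUE, envir = ls_seen)
    ls_rows[[length(ls_rows) + 1L]] <<- list(automaton = a, index = j)
    # edges from a_j to every objective a_i ~> a_j
    for (i in cache$net$automata[[a]]) {
      add_edge(lk, obj_node_key(a, i, j))
      visit_obj(a, i, j)
    }
    invisible(NULL)
  }

  for (obj in roots) {
    visit_ls(obj$automaton, obj$to)
    # the root objective itself (it may start elsewhere than the full fan-in)
    visit_obj(obj$automaton, obj$from, obj$to)
  }

  structure(
    list(
      local_states = if (length(ls_rows)) {
        tibble(automaton = map_chr(ls_rows, "automaton"),
               index = map_int(ls_rows, "index"))
      } else {
        tibble(automaton = character(0), index = integer(0))
      },
      objectives = if (length(obj_rows)) {
        tibble(automaton = map_chr(obj_rows, "automaton"),
               from = map_int(obj_rows, "from"),
               to = map_int(obj_rows, "to"))
      } else {
        tibble(automaton = character(0), from = integer(0), to = integer(0))
      },
      paths = if (length(path_rows)) {
        tibble(
          objective = map_chr(path_rows, "objective"),
          path_id = map_chr(path_rows, "path_id"),
          steps = map(path_rows, "steps")
        )
      } else {
        tibble(objective = character(0), path_id = character(0),
               steps = list())
      },
      edges = tibble(from = edges_from, to = edges_to),
      net = net
    ),
    class = "an_lcg"
  )
}

obj_node_key <- function(a, i, j) paste0(a, ":", i, "~>", j)

#' @export
print.an_lcg <- function(x, ...) {
  cat("Local Causality Graph:", nrow(x$local_states), "local states,",
      nrow(x$objectives), "objectives,", nrow(x$paths), "local paths,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Export an LCG to DOT
#'
#' Local states are drawn as boxes, objectives as plain text, local paths as
#' small circles.
#'
#' @param lcg An `an_lcg`.
#' @param file Optional output path.
#' @return DOT source as a string (invisibly when written to `file`).
#' @export
lcg_dot <- function(lcg, file = NULL) {
  esc <- function(x) gsub('"', '\\\\"', x)
  node_id <- function(key) paste0("n", match(key, all_keys))
  ls_keys <- ls_key(lcg$local_states$automaton, lcg$local_states$index)
  obj_keys <- obj_node_key(lcg$objectives$automaton, lcg$objectives$from,
                           lcg$objectives$to)
  path_keys <- lcg$paths$path_id
  all_keys <- c(ls_keys, obj_keys, path_keys)

  lines <- c("digraph lcg {")
  for (k in ls_keys) {
    lines <- c(lines, sprintf('  %s [shape=box, label="%s"];',
                              node_id(k), esc(k)))
  }
  for (k in obj_keys) {
    lines <- c(lines, sprintf('  %s [shape=plaintext, label="%s"];',
                              node_id(k), esc(k)))
  }
  for (i in seq_along(path_keys)) {
    steps <- lcg$paths$steps[[i]]
    lbl <- if (length(steps)) paste(steps, collapse = ",") else "ε"
    lines <- c(lines, sprintf(
      '  %s [shape=circle, width=0.15, fixedsize=true, xlabel="%s", label=""];',
      node_id(path_keys[i]), esc(lbl)))
  }
  for (r in seq_len(nrow(lcg$edges))) {
    lines <- c(lines, sprintf("  %s -> %s;",
                              node_id(lcg$edges$from[r]),
                              node_id(lcg$edges$to[r])))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(txt))
  }
  txt
}
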
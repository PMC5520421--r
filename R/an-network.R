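#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_lgl keep
NULL

an_error <- function(msg, class, ...) {
  abort(msg, class = c(class, "bifan_error"), ...)
}

#' Construct an automata network
#'
#' An automata network (AN) is a finite set of finite-state automata whose
#' local transitions between local states are conditioned on the local states
#' of *other* automata. The global state of the network assigns one local
#' state to every automaton; under the asynchronous semantics exactly one
#' enabled local transition is applied per step.
#'
#' @param automata Named list mapping automaton identifiers to the number of
#'   local states (a single integer `k`, states are `0:(k-1)`) or to an
#'   integer vector `0:(k-1)`.
#' @param transitions A data frame (or tibble) with columns `automaton`
#'   (character), `origin` (integer), `dest` (integer) and `condition`
#'   (list column of named integer vectors over *other* automata; `NULL` or
#'   an empty vector means an unconditioned transition). An optional `id`
#'   column assigns identifiers; by default ids `t1, t2, ...` are assigned
#'   in row order.
#' @param initial Optional named integer vector giving a declared initial
#'   global state.
#'
#' @return An object of class `an`: a list with elements `automata` (named
#'   list of integer state vectors, automata sorted lexicographically),
#'   `transitions` (tibble with columns `id`, `automaton`, `origin`, `dest`,
#'   `condition`) and `initial`.
#'
#' @examples
#' net <- an_network(
#'   automata = list(a = 2, b = 2),
#'   transitions = tibble::tibble(
#'     automaton = c("a", "b"), origin = c(0L, 0L), dest = c(1L, 1L),
#'     condition = list(c(b = 1L), NULL)
#'   )
#' )
#' net
#' @export
an_network <- function(automata, transitions = NULL, initial = NULL) {
  if (length(automata) == 0 || is.null(names(automata)) ||
      any(!nzchar(names(automata)))) {
    an_error("`automata` must be a non-empty named list", "an_semantic_error")
  }
  if (anyDuplicated(names(automata))) {
    an_error(
      paste0("duplicate automaton declaration: ",
             names(automata)[duplicated(names(automata))][1]),
      "an_semantic_error"
    )
  }
  automata <- lapply(automata, function(x) {
    if (length(x) == 1 && x[1] >= 2) x <- seq.int(0L, as.integer(x) - 1L)
    x <- as.integer(x)
    x
  })
  # canonical ordering: lexicographic (radix: locale-independent)
  automata <- automata[sort(names(automata), method = "radix")]
  for (a in names(automata)) {
    k <- length(automata[[a]])
    if (k < 2 || !identical(automata[[a]], seq.int(0L, k - 1L))) {
      an_error(
        paste0("automaton ", a, " must have >= 2 local states indexed 0..k-1"),
        "an_semantic_error"
      )
    }
  }

  if (is.null(transitions) || nrow(as.data.frame(transitions)) == 0) {
    transitions <- tibble(
      id = character(), automaton = character(),
      origin = integer(), dest = integer(), condition = list()
    )
  } else {
    transitions <- as_tibble(transitions)
    if (!all(c("automaton", "origin", "dest") %in% names(transitions))) {
      an_error("`transitions` needs columns automaton, origin, dest",
               "an_semantic_error")
    }
    if (!"condition" %in% names(transitions)) {
      transitions$condition <- rep(list(NULL), nrow(transitions))
    }
    if (!"id" %in% names(transitions)) {
      transitions$id <- paste0("t", seq_len(nrow(transitions)))
    }
    transitions$origin <- as.integer(transitions$origin)
    transitions$dest <- as.integer(transitions$dest)
    transitions$condition <- lapply(transitions$condition, function(cond) {
      if (is.null(cond) || length(cond) == 0) {
        return(stats::setNames(integer(0), character(0)))
      }
      cond <- stats::setNames(as.integer(cond), names(cond))
      cond[sort(names(cond), method = "radix")]
    })
    transitions <- transitions[, c("id", "automaton", "origin", "dest",
                                   "condition")]
  }

  net <- structure(
    list(automata = automata, transitions = transitions, initial = NULL),
    class = "an"
  )
  validate_an(net)
  if (!is.null(initial)) {
    net$initial <- an_state(net, initial)
  }
  net
}

#' Validate automata-network invariants
#'
#' Checks the structural invariants of an automata network: declared state
#' sets are `0..k-1` with `k >= 2`; every transition references a declared
#' automaton and declared local states; `origin != dest`; conditions carry at
#' most one local state per automaton, never one of the transition's own
#' automaton; transition ids are unique.
#'
#' @param net An `an` object.
#' @return `net`, invisibly. Errors (class `an_semantic_error`) on violation.
#' @export
validate_an <- function(net) {
  stopifnot(inherits(net, "an"))
  tr <- net$transitions
  if (anyDuplicated(tr$id)) {
    an_error(paste0("duplicate transition id: ", tr$id[duplicated(tr$id)][1]),
             "an_semantic_error")
  }
  for (r in seq_len(nrow(tr))) {
    a <- tr$automaton[r]
    where <- paste0(" (transition ", tr$id[r], ")")
    if (!a %in% names(net$automata)) {
      an_error(paste0("undeclared automaton: ", a, where), "an_semantic_error")
    }
    ks <- net$automata[[a]]
    if (!(tr$origin[r] %in% ks) || !(tr$dest[r] %in% ks)) {
      an_error(paste0("undeclared local state of automaton ", a, where),
               "an_semantic_error")
    }
    if (tr$origin[r] == tr$dest[r]) {
      an_error(paste0("self-loop origin = dest in automaton ", a, where),
               "an_semantic_error")
    }
    cond <- tr$condition[[r]]
    if (length(cond)) {
      if (anyDuplicated(names(cond))) {
        an_error(paste0("condition mentions an automaton twice", where),
                 "an_semantic_error")
      }
      if (a %in% names(cond)) {
        an_error(paste0("condition on the transition's own automaton ", a,
                        where), "an_semantic_error")
      }
      for (b in names(cond)) {
        if (!b %in% names(net$automata)) {
          an_error(paste0("undeclared automaton in condition: ", b, where),
                   "an_semantic_error")
        }
        if (!(cond[[b]] %in% net$automata[[b]])) {
          an_error(paste0("undeclared local state ", b, "=", cond[[b]], where),
                   "an_semantic_error")
        }
      }
    }
  }
  invisible(net)
}

#' @export
print.an <- function(x, ...) {
  cat("Automata network:", length(x$automata), "automata,",
      nrow(x$transitions), "local transitions\n")
  for (a in names(x$automata)) {
    cat("  ", a, ": states 0..", length(x$automata[[a]]) - 1L, "\n", sep = "")
  }
  if (nrow(x$transitions)) print(x$transitions, n = 10)
  if (!is.null(x$initial)) {
    cat("initial:", format_an_state(x$initial), "\n")
  }
  invisible(x)
}

#' Build a global state
#'
#' @param net An `an` object.
#' @param state A named integer vector (one entry per automaton), or a string
#'   such as `"a=0,b=1,c=0"`.
#' @return A named integer vector over all automata, in canonical
#'   (lexicographic) automaton order.
#' @examples
#' net <- an_builtin("fig1")$net
#' an_state(net, "a=0,b=0,c=0")
#' @export
an_state <- function(net, state) {
  stopifnot(inherits(net, "an"))
  if (is.character(state) && length(state) == 1 && is.null(names(state))) {
    state <- parse_assignments(state)
  }
  autos <- names(net$automata)
  if (is.null(names(state)) || !setequal(names(state), autos) ||
      length(state) != length(autos)) {
    an_error("state must assign exactly one value to every automaton",
             "an_semantic_error")
  }
  s <- stats::setNames(as.integer(state[autos]), autos)
  for (a in autos) {
    if (!(s[[a]] %in% net$automata[[a]])) {
      an_error(paste0("undeclared local state ", a, "=", s[[a]]),
               "an_semantic_error")
    }
  }
  s
}

#' Canonical string form of a global state
#'
#' @param s Named integer vector as returned by [an_state()].
#' @return A string `"a=0,b=1,..."` with automata in canonical order.
#' @export
format_an_state <- function(s) {
  paste0(names(s), "=", unname(s), collapse = ",")
}

# fast internal key: values only (automaton order is canonical and fixed)
state_key <- function(s) paste(s, collapse = ",")

# parse "a=0, b=1" into a named integer vector
parse_assignments <- function(text, line = NULL) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec('^\\s*"?([^"=\\s]+)"?\\s*=\\s*([0-9]+)\\s*$', p, perl = TRUE))[[1]]
    if (length(m) != 3) {
      an_error(paste0("malformed assignment: '", trimws(p), "'",
                      if (!is.null(line)) paste0(" at line ", line)),
               "an_parse_error")
    }
    out[m[2]] <- as.integer(m[3])
  }
  out
}

#' Designate a goal local state
#'
#' A goal is a local state `g_j` of some automaton `g`; a global state
#' "contains the goal" when its `g` coordinate equals `j`.
#'
#' @param automaton Automaton identifier, or a string `"a=2"`.
#' @param index Local-state index (omit when using the string form).
#' @return An object of class `an_goal`.
#' @examples
#' an_goal("a", 2)
#' an_goal("a=2")
#' @export
an_goal <- function(automaton, index = NULL) {
  if (is.null(index)) {
    asn <- parse_assignments(automaton)
    if (length(asn) != 1) {
      an_error("goal must name a single local state", "an_semantic_error")
    }
    automaton <- names(asn)
    index <- asn[[1]]
  }
  structure(list(automaton = automaton, index = as.integer(index)),
            class = "an_goal")
}

#' @export
print.an_goal <- function(x, ...) {
  cat("Goal local state:", paste0(x$automaton, "=", x$index), "\n")
  invisible(x)
}

check_goal <- function(net, goal) {
  if (!inherits(goal, "an_goal")) goal <- an_goal(goal)
  if (!goal$automaton %in% names(net$automata) ||
      !(goal$index %in% net$automata[[goal$automaton]])) {
    an_error(paste0("goal references undeclared local state ",
                    goal$automaton, "=", goal$index), "an_semantic_error")
  }
  goal
}

#' Serialize an automata network to its canonical text form
#'
#' The canonical dialect is line-oriented UTF-8: one `automaton` declaration
#' per automaton (lexicographic order), one transition statement per local
#' transition (id order) and an optional trailing `initial` statement.
#' `serialize_an(parse_an(x))` reparses to an identical network.
#'
#' @param net An `an` object.
#' @param file Optional path; when given the text is written there.
#' @return The serialized text as a single string (invisibly when `file` is
#'   given).
#' @examples
#' cat(serialize_an(an_builtin("fig1")$net))
#' @export
serialize_an <- function(net, file = NULL) {
  stopifnot(inherits(net, "an"))
  lines <- character(0)
  for (a in names(net$automata)) {
    lines <- c(lines, sprintf('automaton "%s" [%s]', a,
                              paste(net$automata[[a]], collapse = ", ")))
  }
  tr <- net$transitions
  for (r in seq_len(nrow(tr))) {
    stmt <- sprintf('"%s" %d -> %d', tr$automaton[r], tr$origin[r], tr$dest[r])
    cond <- tr$condition[[r]]
    if (length(cond)) {
      stmt <- paste0(stmt, " when ",
                     paste0('"', names(cond), '"=', unname(cond),
                            collapse = ", "))
    }
    lines <- c(lines, stmt)
  }
  if (!is.null(net$initial)) {
    lines <- c(lines, paste0("initial ",
                             paste0('"', names(net$initial), '"=',
                                    unname(net$initial), collapse = ", ")))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(text))
  }
  text
}
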
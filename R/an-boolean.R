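# --- Boolean expression parsing (recursive descent) -------------------------
#
# Grammar: expr := term ('|' term)* ; term := unary ('&' unary)* ;
#          unary := '!' unary | '(' expr ')' | ident | '0' | '1'
# An expression is represented as a nested list AST.

bn_tokenize <- function(text) {
  rx <- "[A-Za-z_][A-Za-z0-9_.]*|[01]|[!&|()]"
  toks <- regmatches(text, gregexpr(rx, text))[[1]]
  residue <- gsub(rx, "", text)
  residue <- gsub("\\s", "", residue)
  if (nzchar(residue)) {
    an_error(paste0("non-Boolean expression: unexpected '", residue,
                    "' in '", text, "'"), "an_parse_error")
  }
  toks
}

bn_parse_expr <- function(text) {
  toks <- bn_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function() an_error(paste0("non-Boolean expression: '", text, "'"),
                              "an_parse_error")

  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && peek() == "|") {
      take()
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_unary()
    while (!is.na(peek()) && peek() == "&") {
      take()
      node <- list(op = "and", lhs = node, rhs = parse_unary())
    }
    node
  }
  parse_unary <- function() {
    t <- peek()
    if (is.na(t)) fail()
    if (t == "!") { take(); return(list(op = "not", arg = parse_unary())) }
    if (t == "(") {
      take()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail()
      take()
      return(node)
    }
    if (t %in% c("0", "1")) { take(); return(list(op = "const",
                                                  value = t == "1")) }
    if (grepl("^[A-Za-z_]", t)) { take(); return(list(op = "var", name = t)) }
    fail()
  }

  node <- parse_expr()
  if (!is.na(peek())) fail()
  node
}

bn_vars <- function(node) {
  switch(node$op,
    var = node$name,
    const = character(0),
    not = bn_vars(node$arg),
    unique(c(bn_vars(node$lhs), bn_vars(node$rhs)))
  )
}

bn_eval <- function(node, env) {
  switch(node$op,
    var = env[[node$name]],
    const = node$value,
    not = !bn_eval(node$arg, env),
    and = bn_eval(node$lhs, env) && bn_eval(node$rhs, env),
    or = bn_eval(node$lhs, env) || bn_eval(node$rhs, env)
  )
}

# --- Prime implicants by truth-table minimization ----------------------------
#
# `f` is a logical vector over the full truth table of `vars` (rows in binary
# counting order, vars[1] the most significant bit). A partial assignment is
# an implicant when f is true on all its completions; it is prime when no
# literal can be dropped. Enumerated in increasing literal count, so primes
# are exactly the implicants with no previously-found prime as a
# sub-assignment. Deterministic order: literal count, then lexicographic on
# the serialized literals.
prime_implicants <- function(f, vars) {
  k <- length(vars)
  if (k == 0) {
    return(if (isTRUE(f[1])) list(stats::setNames(integer(0), character(0)))
           else list())
  }
  if (!any(f)) return(list())

  # truth-table grid in binary counting order, vars[1] most significant
  grid <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  colnames(grid) <- vars

  covers <- function(assign_vals, assign_vars) {
    rows <- rep(TRUE, nrow(grid))
    for (ii in seq_along(assign_vars)) {
      rows <- rows & grid[, assign_vars[ii]] == assign_vals[ii]
    }
    rows
  }

  primes <- list()
  prime_keys <- character(0)
  for (size in 0:k) {
    subsets <- utils::combn(k, size, simplify = FALSE)
    if (size == 0) subsets <- list(integer(0))
    cand <- list()
    for (ss in subsets) {
      vs <- vars[ss]
      vals_grid <- if (size > 0) {
        as.matrix(expand.grid(rep(list(0:1), size)))
      } else {
        matrix(integer(0), nrow = 1, ncol = 0)
      }
      for (r in seq_len(nrow(vals_grid))) {
        vals <- as.integer(vals_grid[r, ])
        rows <- covers(vals, vs)
        if (!all(f[rows])) next
        # prime iff no smaller prime subsumes it
        asn <- stats::setNames(vals, vs)
        subsumed <- any(map_lgl(primes, function(p) {
          length(p) < length(asn) &&
            all(names(p) %in% names(asn)) &&
            all(asn[names(p)] == p)
        }))
        if (!subsumed) cand[[length(cand) + 1L]] <- asn[order(names(asn),
                                                              method = "radix")]
      }
    }
    if (length(cand)) {
      keys <- map_chr(cand, function(p) paste0(names(p), "=", p,
                                               collapse = ","))
      cand <- cand[order(keys, method = "radix")]
      primes <- c(primes, cand)
    }
  }
  primes
}

#' Encode a Boolean network as an automata network
#'
#' Reads a `targets, factors` table of Boolean functions and produces the
#' equivalent asynchronous automata network: one two-state automaton per
#' node; for node `x` with update function `f`, one transition `x: 0 -> 1`
#' per prime implicant of `f` restricted to `x = 0`, and one `x: 1 -> 0` per
#' prime implicant of `!f` restricted to `x = 1`. The restriction removes `x`
#' from its own conditions, as transition conditions may only mention other
#' automata. The asynchronous state graphs of the Boolean network and its
#' encoding are identical.
#'
#' @param text Table text (string, lines, or file path): header
#'   `targets, factors`, then rows `<node>, <Boolean expression>` using
#'   `&`, `|`, `!`, parentheses and constants `0`/`1`.
#' @param file Set `TRUE` to force reading `text` as a path.
#' @return An `an` object with one 2-state automaton per node.
#' @examples
#' encode_boolean_network(c(
#'   "targets, factors",
#'   "x, a & !b",
#'   "a, a",
#'   "b, b"
#' ))
#' @export
encode_boolean_network <- function(text, file = FALSE) {
  if (file || (length(text) == 1 && !grepl("\n", text) && file.exists(text))) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- lines[nzchar(trimws(lines))]
  header <- tolower(gsub("\\s", "", lines[1]))
  if (header != "targets,factors") {
    an_error("expected header 'targets, factors'", "an_parse_error")
  }

  rows <- lines[-1]
  nodes <- character(0)
  exprs <- list()
  for (i in seq_along(rows)) {
    comma <- regexpr(",", rows[i], fixed = TRUE)
    if (comma < 0) {
      an_error(paste0("line ", i + 1, ": expected '<node>, <expression>'"),
               "an_parse_error")
    }
    node <- trimws(substr(rows[i], 1, comma - 1))
    expr <- trimws(substr(rows[i], comma + 1, nchar(rows[i])))
    if (node %in% nodes) {
      an_error(paste0("line ", i + 1, ": duplicate node ", node),
               "an_parse_error")
    }
    nodes <- c(nodes, node)
    exprs[[node]] <- bn_parse_expr(expr)
  }

  for (node in nodes) {
    unknown <- setdiff(bn_vars(exprs[[node]]), nodes)
    if (length(unknown)) {
      an_error(paste0("unknown node in factors of ", node, ": ",
                      unknown[1]), "an_parse_error")
    }
  }

  tr_rows <- list()
  for (node in nodes) {
    ast <- exprs[[node]]
    vars <- sort(bn_vars(ast), method = "radix")
    others <- setdiff(vars, node)
    if (length(others) > 16) {
      an_error(paste0("node ", node, " has too many regulators (",
                      length(others), ")"), "an_semantic_error")
    }
    truth <- function(self_value, negate) {
      k <- length(others)
      n_rows <- 2^k
      out <- logical(n_rows)
      grid <- if (k > 0) {
        as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
      } else {
        matrix(integer(0), nrow = 1, ncol = 0)
      }
      colnames(grid) <- others
      for (r in seq_len(nrow(grid))) {
        env <- as.list(grid[r, , drop = TRUE] == 1L)
        names(env) <- others
        env[[node]] <- self_value
        v <- bn_eval(ast, env)
        out[r] <- if (negate) !v else v
      }
      out
    }
    up <- prime_implicants(truth(FALSE, FALSE), others)   # f | x=0
    down <- prime_implicants(truth(TRUE, TRUE), others)   # !f | x=1
    for (p in up) {
      tr_rows[[length(tr_rows) + 1L]] <-
        list(automaton = node, origin = 0L, dest = 1L, condition = p)
    }
    for (p in down) {
      tr_rows[[length(tr_rows) + 1L]] <-
        list(automaton = node, origin = 1L, dest = 0L, condition = p)
    }
  }

  transitions <- if (length(tr_rows)) {
    tibble(
      automaton = map_chr(tr_rows, "automaton"),
      origin = map_int(tr_rows, "origin"),
      dest = map_int(tr_rows, "dest"),
      condition = map(tr_rows, "condition")
    )
  } else {
    NULL
  }
  an_network(stats::setNames(rep(list(0:1), length(nodes)), nodes),
             transitions)
}
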
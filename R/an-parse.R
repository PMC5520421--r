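#' Parse an automata network from text
#'
#' Reads the canonical textual dialect: one statement per line, `#` starts a
#' comment. Statements are
#' \preformatted{
#' automaton "<name>" [0, 1, ..., k-1]
#' "<name>" <i> -> <j>
#' "<name>" <i> -> <j> when "<b>"=<k>, "<c>"=<m>, ...
#' initial "<name>"=<i>, ...
#' }
#' Transition ids `t1, t2, ...` are assigned in file order.
#'
#' @param text Model text: a single string, a character vector of lines, or a
#'   path to a file (when `file = TRUE` or when `text` names an existing
#'   file and contains no newline).
#' @param file Set to `TRUE` to force interpreting `text` as a path.
#' @return An `an` object (see [an_network()]).
#' @examples
#' parse_an(c(
#'   'automaton "x" [0, 1]',
#'   'automaton "y" [0, 1]',
#'   '"x" 0 -> 1 when "y"=1'
#' ))
#' @export
parse_an <- function(text, file = FALSE) {
  if (file || (length(text) == 1 && !grepl("\n", text) && file.exists(text))) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }

  automata <- list()
  trs <- list()
  initial_raw <- NULL

  rx_autom <- '^automaton\\s+"([^"]+)"\\s*\\[([0-9,\\s]*)\\]\\s*$'
  rx_trans <- '^"([^"]+)"\\s+([0-9]+)\\s*->\\s*([0-9]+)(\\s+when\\s+(.*))?$'
  rx_init  <- '^initial\\s+(.+)$'

  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next

    m <- regmatches(ln, regexec(rx_autom, ln, perl = TRUE))[[1]]
    if (length(m)) {
      name <- m[2]
      if (name %in% names(automata)) {
        an_error(paste0("line ", i, ": duplicate automaton ", name),
                 "an_parse_error")
      }
      idx <- suppressWarnings(as.integer(trimws(
        strsplit(m[3], ",", fixed = TRUE)[[1]])))
      if (length(idx) < 2 || anyNA(idx) ||
          !identical(idx, seq.int(0L, length(idx) - 1L))) {
        an_error(paste0("line ", i, ": automaton ", name,
                        " must declare states [0, 1, ..., k-1] with k >= 2"),
                 "an_parse_error")
      }
      automata[[name]] <- idx
      next
    }

    m <- regmatches(ln, regexec(rx_trans, ln, perl = TRUE))[[1]]
    if (length(m)) {
      cond <- if (nzchar(m[5]) && nzchar(trimws(m[6]))) {
        parse_assignments(m[6], line = i)
      } else {
        integer(0)
      }
      trs[[length(trs) + 1L]] <- list(
        automaton = m[2], origin = as.integer(m[3]), dest = as.integer(m[4]),
        condition = cond, line = i
      )
      next
    }

    m <- regmatches(ln, regexec(rx_init, ln, perl = TRUE))[[1]]
    if (length(m)) {
      if (!is.null(initial_raw)) {
        an_error(paste0("line ", i, ": duplicate initial statement"),
                 "an_parse_error")
      }
      initial_raw <- parse_assignments(m[2], line = i)
      next
    }

    an_error(paste0("line ", i, ": syntax error near '",
                    substr(ln, 1, 40), "'"), "an_parse_error")
  }

  if (length(automata) == 0) {
    an_error("no automaton declarations found", "an_parse_error")
  }

  transitions <- if (length(trs)) {
    tibble(
      id = paste0("t", seq_along(trs)),
      automaton = map_chr(trs, "automaton"),
      origin = map_int(trs, "origin"),
      dest = map_int(trs, "dest"),
      condition = map(trs, "condition")
    )
  } else {
    NULL
  }

  net <- an_network(automata, transitions)
  if (!is.null(initial_raw)) net$initial <- an_state(net, initial_raw)
  net
}
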
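# Rule expressions and the rule-file parser.
#
# A rule expression is a finite tree of nodes of kind "var", "not", "and"
# or "or". N-ary chains written as `a | b | c` are canonicalised to
# left-folded binary trees ((a | b) | c), which makes the operator-site
# indexing used by the robustness analysis well-defined.

bool_var <- function(name) structure(list(kind = "var", name = name), class = "bool_rule")
bool_not <- function(arg) structure(list(kind = "not", arg = arg), class = "bool_rule")
bool_and <- function(lhs, rhs) structure(list(kind = "and", lhs = lhs, rhs = rhs), class = "bool_rule")
bool_or  <- function(lhs, rhs) structure(list(kind = "or",  lhs = lhs, rhs = rhs), class = "bool_rule")

rule_variables <- function(e) {
  switch(e$kind,
    var = e$name,
    not = rule_variables(e$arg),
    unique(c(rule_variables(e$lhs), rule_variables(e$rhs))))
}

rename_rule_variables <- function(e, map) {
  switch(e$kind,
    var = if (e$name %in% names(map)) bool_var(unname(map[[e$name]])) else e,
    not = bool_not(rename_rule_variables(e$arg, map)),
    and = bool_and(rename_rule_variables(e$lhs, map), rename_rule_variables(e$rhs, map)),
    or  = bool_or(rename_rule_variables(e$lhs, map), rename_rule_variables(e$rhs, map)))
}

# --- tokenizer -------------------------------------------------------------

tokenize_expr <- function(s, line) {
  bad <- regexpr("[^A-Za-z0-9_.!&|()[:space:]]", s)
  if (bad > 0) {
    stop(sprintf("syntax error at line %d, column %d: unexpected character '%s'",
                 line, bad, substr(s, bad, bad)), call. = FALSE)
  }
  m <- gregexpr("[A-Za-z0-9_.]+|[!&|()]", s)[[1]]
  if (m[1] == -1L) {
    stop(sprintf("syntax error at line %d: empty expression", line), call. = FALSE)
  }
  list(text = regmatches(s, list(m))[[1]], col = as.integer(m), line = line)
}

# --- recursive-descent parser (precedence NOT > AND > OR) ------------------

parse_expr_tokens <- function(tk) {
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  peek <- function() if (st$i <= length(tk$text)) tk$text[st$i] else ""
  advance <- function() st$i <- st$i + 1L
  fail <- function(what) {
    col <- if (st$i <= length(tk$col)) tk$col[st$i] else nchar_end(tk)
    stop(sprintf("syntax error at line %d, column %d: %s", tk$line, col, what),
         call. = FALSE)
  }
  nchar_end <- function(tk) {
    if (length(tk$col)) tk$col[length(tk$col)] + nchar(tk$text[length(tk$text)]) else 1L
  }

  p_atom <- function() {
    t <- peek()
    if (t == "!") { advance(); return(bool_not(p_atom())) }
    if (t == "(") {
      advance()
      e <- p_or()
      if (peek() != ")") fail("expected ')'")
      advance()
      return(e)
    }
    if (grepl("^[A-Za-z0-9_.]+$", t)) { advance(); return(bool_var(t)) }
    fail(if (t == "") "unexpected end of expression" else sprintf("unexpected '%s'", t))
  }
  p_and <- function() {
    e <- p_atom()
    while (peek() == "&") { advance(); e <- bool_and(e, p_atom()) }
    e
  }
  p_or <- function() {
    e <- p_and()
    while (peek() == "|") { advance(); e <- bool_or(e, p_and()) }
    e
  }

  e <- p_or()
  if (peek() != "") fail(sprintf("trailing input '%s'", peek()))
  e
}

# --- model constructor -----------------------------------------------------

new_boolean_model <- function(nodes, rules, inputs, aliases = character()) {
  structure(list(nodes = nodes, rules = rules, inputs = inputs, aliases = aliases),
            class = "boolean_model")
}

#' Parse a Boolean model from rule-file text
#'
#' The rule file holds one `Node = expression` statement per line, with
#' `#` comments and `input Node` declarations for free constants (nodes
#' with no rule, held fixed during dynamics but branched over when
#' enumerating stable states). Expressions use `!` (NOT), `&` (AND) and
#' `|` (OR) with precedence `!` > `&` > `|`, and parentheses. N-ary
#' chains are stored as left-folded binary trees.
#'
#' @param text character vector of lines (or a single string containing
#'   newlines) with the rule-file content.
#' @param aliases named character vector mapping alternate spellings to
#'   canonical node names (e.g. `c(ECM = "ECMicroenv")`).
#' @return A `boolean_model`: list with `nodes` (declaration order),
#'   `rules` (named list of rule expressions; `NULL` for inputs),
#'   `inputs` and `aliases`.
#' @seealso [read_boolean_model()], [format_boolean_model()],
#'   [enumerate_stable_states()]
#' @export
#' @examples
#' m <- parse_boolean_model(c("input u", "x = u & !y", "y = x | y"))
#' m$nodes
parse_boolean_model <- function(text, aliases = character()) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)

  nodes <- character()
  rules <- list()
  inputs <- character()

  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    if (grepl("^input\\s+", s)) {
      nm <- trimws(sub("^input\\s+", "", s))
      if (!grepl("^[A-Za-z0-9_.]+$", nm)) {
        stop(sprintf("syntax error at line %d: invalid input declaration '%s'", ln, s),
             call. = FALSE)
      }
      if (nm %in% nodes) stop(sprintf("line %d: duplicate declaration of node '%s'", ln, nm),
                              call. = FALSE)
      nodes <- c(nodes, nm)
      inputs <- c(inputs, nm)
      next
    }
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq <= 0) stop(sprintf("syntax error at line %d: expected 'Node = expression'", ln),
                      call. = FALSE)
    nm <- trimws(substr(s, 1L, eq - 1L))
    if (!grepl("^[A-Za-z0-9_.]+$", nm)) {
      stop(sprintf("syntax error at line %d: invalid node name '%s'", ln, nm), call. = FALSE)
    }
    if (nm %in% names(rules)) stop(sprintf("line %d: duplicate rule for node '%s'", ln, nm),
                                   call. = FALSE)
    if (nm %in% inputs) stop(sprintf("line %d: node '%s' declared as input but given a rule",
                                     ln, nm), call. = FALSE)
    expr_text <- substr(s, eq + 1L, nchar(s))
    tk <- tokenize_expr(expr_text, ln)
    tk$col <- tk$col + eq  # report columns relative to the full line
    e <- parse_expr_tokens(tk)
    if (length(aliases)) e <- rename_rule_variables(e, aliases)
    if (!nm %in% nodes) nodes <- c(nodes, nm)
    rules[[nm]] <- e
  }

  referenced <- unique(unlist(lapply(rules, rule_variables), use.names = FALSE))
  unknown <- setdiff(referenced, nodes)
  if (length(unknown)) {
    stop("reference to undeclared node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  new_boolean_model(nodes, rules, inputs, aliases)
}

#' Read a Boolean model from a rule file
#'
#' @param path path to a rule file (see [parse_boolean_model()] for the format).
#' @inheritParams parse_boolean_model
#' @return A `boolean_model`.
#' @export
read_boolean_model <- function(path, aliases = character()) {
  parse_boolean_model(readLines(path, warn = FALSE), aliases = aliases)
}

# --- serialisation ---------------------------------------------------------

rule_precedence <- c(or = 1L, and = 2L, not = 3L, var = 4L)

format_rule <- function(e, parent = 0L, right = FALSE) {
  p <- rule_precedence[[e$kind]]
  s <- switch(e$kind,
    var = e$name,
    not = paste0("!", format_rule(e$arg, parent = 3L)),
    and = paste0(format_rule(e$lhs, parent = p), " & ",
                 format_rule(e$rhs, parent = p, right = TRUE)),
    or  = paste0(format_rule(e$lhs, parent = p), " | ",
                 format_rule(e$rhs, parent = p, right = TRUE)))
  # parenthesise when binding would change on re-parse; right operands of
  # equal precedence keep their grouping so operator sites survive round-trips
  if (p < parent || (right && p == parent && e$kind %in% c("and", "or"))) {
    s <- paste0("(", s, ")")
  }
  s
}

#' Serialise a Boolean model to rule-file text
#'
#' Re-parsing the output yields a model with identical rules (up to the
#' canonical binary form, which serialisation preserves).
#'
#' @param model a `boolean_model`.
#' @return Character vector of rule-file lines.
#' @export
format_boolean_model <- function(model) {
  out <- if (length(model$inputs)) paste("input", model$inputs) else character()
  ruled <- setdiff(model$nodes, model$inputs)
  c(out, vapply(ruled, function(nd) paste(nd, "=", format_rule(model$rules[[nd]])),
                character(1)))
}

#' Write a Boolean model to a rule file
#' @inheritParams format_boolean_model
#' @param path output file path.
#' @export
write_boolean_model <- function(model, path) {
  writeLines(format_boolean_model(model), path)
  invisible(path)
}

#' Export a model to BoolNet-style "targets, factors" CSV
#'
#' One row per ruled node with its rule expression; inputs are written as
#' self-activating factors (`Node, Node`), the usual BoolNet convention
#' for constant nodes.
#'
#' @inheritParams format_boolean_model
#' @param path output file path.
#' @export
export_boolnet <- function(model, path) {
  lines <- c("targets, factors")
  for (nd in model$nodes) {
    rhs <- if (nd %in% model$inputs) nd else format_rule(model$rules[[nd]])
    lines <- c(lines, paste0(nd, ", ", rhs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.boolean_model <- function(x, ...) {
  cat(sprintf("Boolean model: %d nodes (%d inputs, %d ruled)\n",
              length(x$nodes), length(x$inputs), length(x$nodes) - length(x$inputs)))
  if (length(x$inputs)) cat("inputs:", paste(x$inputs, collapse = ", "), "\n")
  invisible(x)
}
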
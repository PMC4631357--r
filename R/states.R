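# Network states, clamps, rule evaluation, asynchronous successors and
# exact stable-state enumeration.

#' Construct a network state
#'
#' A network state is a named integer vector with one 0/1 entry per model
#' node, in model node order.
#'
#' @param model a `boolean_model`.
#' @param bits named or unnamed 0/1 vector; unnamed vectors must follow
#'   model node order, named vectors are reordered and checked for
#'   completeness.
#' @return Named integer vector over all model nodes.
#' @export
network_state <- function(model, bits) {
  if (is.null(names(bits))) {
    if (length(bits) != length(model$nodes)) {
      stop("state must assign all ", length(model$nodes), " nodes", call. = FALSE)
    }
    bits <- setNames(as.integer(bits), model$nodes)
  } else {
    missing <- setdiff(model$nodes, names(bits))
    if (length(missing)) {
      stop("state is missing node(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    bits <- setNames(as.integer(bits[model$nodes]), model$nodes)
  }
  if (!all(bits %in% 0:1)) stop("state values must be 0 or 1", call. = FALSE)
  bits
}

validate_clamps <- function(model, clamps) {
  if (is.null(clamps) || length(clamps) == 0L) {
    return(setNames(integer(0), character(0)))
  }
  if (is.null(names(clamps)) || any(!nzchar(names(clamps)))) {
    stop("clamps must be a named 0/1 vector, e.g. c(NICD = 1, p53 = 0)", call. = FALSE)
  }
  if (anyDuplicated(names(clamps))) {
    stop("a node appears more than once in the clamp set", call. = FALSE)
  }
  unknown <- setdiff(names(clamps), model$nodes)
  if (length(unknown)) {
    stop("clamp on unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cl <- as.integer(clamps)
  if (!all(cl %in% 0:1)) stop("clamp values must be 0 or 1", call. = FALSE)
  setNames(cl, names(clamps))
}

eval_rule_expr <- function(e, state) {
  switch(e$kind,
    var = state[[e$name]],
    not = 1L - eval_rule_expr(e$arg, state),
    and = { if (eval_rule_expr(e$lhs, state) == 0L) 0L else eval_rule_expr(e$rhs, state) },
    or  = { if (eval_rule_expr(e$lhs, state) == 1L) 1L else eval_rule_expr(e$rhs, state) })
}

#' Evaluate the rule of a node under a state
#'
#' @inheritParams network_state
#' @param node node name; must carry a rule (inputs are constants and
#'   have none).
#' @param state a network state (named 0/1 vector over all nodes).
#' @return 0 or 1.
#' @export
evaluate_rule <- function(model, node, state) {
  if (!node %in% model$nodes) stop("unknown node: ", node, call. = FALSE)
  if (node %in% model$inputs) {
    stop("node '", node, "' is an input and has no rule; treat it as a constant",
         call. = FALSE)
  }
  state <- network_state(model, state)
  eval_rule_expr(model$rules[[node]], state)
}

#' Asynchronous successor states
#'
#' Under asynchronous update exactly one node changes per transition. The
#' successors of a state are the single-bit flips of every non-clamped,
#' ruled node whose rule value differs from its current value; inputs and
#' clamped nodes never flip. The state is stable iff the set is empty.
#'
#' @inheritParams evaluate_rule
#' @param clamps named 0/1 vector of forced nodes (GoF = 1, LoF = 0), or
#'   `NULL`. The state must already hold the clamped values.
#' @return List of successor states (named 0/1 vectors).
#' @export
async_successors <- function(model, state, clamps = NULL) {
  state <- network_state(model, state)
  clamps <- validate_clamps(model, clamps)
  if (length(clamps) && any(state[names(clamps)] != clamps)) {
    stop("state does not hold the clamped values", call. = FALSE)
  }
  succ <- list()
  for (nd in setdiff(setdiff(model$nodes, model$inputs), names(clamps))) {
    v <- eval_rule_expr(model$rules[[nd]], state)
    if (v != state[[nd]]) {
      s2 <- state
      s2[[nd]] <- v
      succ[[length(succ) + 1L]] <- s2
    }
  }
  succ
}

#' Hamming distance between two network states
#'
#' @param a,b network states over the same node set (named 0/1 vectors).
#' @return Number of nodes at which the states differ.
#' @export
hamming_distance <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) || !setequal(names(a), names(b))) {
    stop("states must be named over the same node set", call. = FALSE)
  }
  sum(a[names(b)] != b)
}

# --- compilation to postfix tokens ----------------------------------------

# Flatten a rule to postfix tokens (>= 0: 0-based node index; -1 NOT;
# -2 AND; -3 OR). `sites` gives, for each binary operator in left-to-right
# (in-order) reading of the rule as written, its 0-based token position.
flatten_rule <- function(e, idx) {
  switch(e$kind,
    var = list(tokens = idx[[e$name]], sites = integer()),
    not = {
      f <- flatten_rule(e$arg, idx)
      list(tokens = c(f$tokens, -1L), sites = f$sites)
    },
    {
      L <- flatten_rule(e$lhs, idx)
      R <- flatten_rule(e$rhs, idx)
      op <- if (e$kind == "and") -2L else -3L
      nl <- length(L$tokens)
      list(tokens = c(L$tokens, R$tokens, op),
           sites = c(L$sites, nl + length(R$tokens), R$sites + nl))
    })
}

compile_boolean_model <- function(model) {
  idx <- setNames(seq_along(model$nodes) - 1L, model$nodes)
  tokens <- vector("list", length(model$nodes))
  sites <- vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[i]
    if (nd %in% model$inputs) next
    f <- flatten_rule(model$rules[[nd]], idx)
    tokens[[i]] <- f$tokens
    sites[[i]] <- f$sites
  }
  list(nodes = model$nodes, tokens = tokens, sites = sites)
}

stable_states_from_tokens <- function(compiled, clamps_idx0, clamps_val) {
  m <- cpp_stable_states(compiled$tokens, as.integer(clamps_idx0), as.integer(clamps_val))
  colnames(m) <- compiled$nodes
  if (nrow(m) > 1L) {
    m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  }
  m
}

#' Enumerate all stable states of a model
#'
#' A stable state is a full assignment in which every non-clamped ruled
#' node equals the value of its rule; clamped nodes hold their forced
#' value, and inputs are free constants, so every input combination is
#' explored. The search is exact branch-and-propagate constraint solving
#' over partial assignments (not enumeration of the full state space).
#'
#' @inheritParams async_successors
#' @return Integer matrix, one row per stable state (rows in
#'   lexicographic order over the node-order bit string), one column per
#'   node.
#' @export
#' @examples
#' m <- load_metastasis_model()
#' nrow(enumerate_stable_states(m))  # 9
enumerate_stable_states <- function(model, clamps = NULL) {
  clamps <- validate_clamps(model, clamps)
  compiled <- compile_boolean_model(model)
  stable_states_from_tokens(compiled,
                            match(names(clamps), model$nodes) - 1L,
                            unname(clamps))
}

# --- stable-state table IO -------------------------------------------------

#' Write stable states as a node-by-state TSV table
#'
#' One row per node and one column per state, after the usual
#' presentation of logical-model stable states.
#'
#' @param states integer matrix as returned by [enumerate_stable_states()]
#'   (states in rows).
#' @param path output file path.
#' @param node_order optional character vector giving the row order.
#' @param state_names optional column labels; defaults to S1, S2, ...
#' @export
write_stable_states <- function(states, path, node_order = NULL, state_names = NULL) {
  tab <- t(states)
  if (!is.null(node_order)) tab <- tab[node_order, , drop = FALSE]
  colnames(tab) <- if (is.null(state_names)) paste0("S", seq_len(ncol(tab))) else state_names
  df <- data.frame(node = rownames(tab), tab, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a node-by-state stable-state TSV table
#'
#' @param path file written by [write_stable_states()] (or the bundled
#'   wild-type fixture).
#' @return Integer matrix, nodes in rows, states in columns.
#' @export
read_stable_states <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
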
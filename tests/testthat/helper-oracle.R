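# Independent oracles used across the suite.
#
# The brute-force stable-state oracle evaluates every rule over the full
# 2^n state grid with plain vectorised R on the parsed rule trees; it
# shares nothing with the branch-and-propagate C++ solver beyond the
# parser.

oracle_eval <- function(e, bits) {
  switch(e$kind,
    var = bits[, e$name],
    not = 1L - oracle_eval(e$arg, bits),
    and = pmin(oracle_eval(e$lhs, bits), oracle_eval(e$rhs, bits)),
    or  = pmax(oracle_eval(e$lhs, bits), oracle_eval(e$rhs, bits)))
}

brute_stable_states <- function(model, clamps = NULL) {
  n <- length(model$nodes)
  stopifnot(n <= 16)
  grid <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- model$nodes
  storage.mode(grid) <- "integer"
  if (!is.null(clamps) && length(clamps)) {
    keep <- rep(TRUE, nrow(grid))
    for (nd in names(clamps)) keep <- keep & grid[, nd] == clamps[[nd]]
    grid <- grid[keep, , drop = FALSE]
  }
  stable <- rep(TRUE, nrow(grid))
  free_ruled <- setdiff(setdiff(model$nodes, model$inputs), names(clamps))
  for (nd in free_ruled) {
    stable <- stable & (oracle_eval(model$rules[[nd]], grid) == grid[, nd])
  }
  grid[stable, , drop = FALSE]
}

state_keys <- function(states) {
  if (nrow(states) == 0L) return(character())
  unname(apply(states, 1L, paste, collapse = ""))
}

# a state matrix pair is equal as a set of full assignments
expect_same_states <- function(a, b) {
  expect_setequal(state_keys(a[, colnames(b), drop = FALSE]), state_keys(b))
}
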
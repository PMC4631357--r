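# Continuous-time Markov (Gillespie) simulation of the asynchronous
# Boolean dynamics, and an exact absorption solve for small state spaces.

#' Simulation configuration
#'
#' @param n_trajectories number of independent trajectories.
#' @param max_time simulated-time horizon (time units; all flip rates
#'   default to 1 per time unit, so 100 units is far beyond the mixing
#'   time of the 32-node model).
#' @param rate_up,rate_down per-node transition rates for 0 to 1 and 1
#'   to 0 flips (time^-1).
#' @param seed master seed; each trajectory draws from its own
#'   independent substream, so increasing `n_trajectories` does not
#'   reshuffle earlier trajectories.
#' @param initial named 0/1 vector fixing the initial value of some
#'   nodes; all other nodes start i.i.d. uniform on \{0, 1\}. `NULL`
#'   (the default) randomises every node.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trajectories = 1000, max_time = 100,
                       rate_up = 1, rate_down = 1, seed = 1, initial = NULL) {
  stopifnot(n_trajectories >= 1, max_time > 0, rate_up > 0, rate_down > 0)
  structure(list(n_trajectories = as.integer(n_trajectories),
                 max_time = max_time, rate_up = rate_up, rate_down = rate_down,
                 seed = seed, initial = initial),
            class = "sim_config")
}

#' Sample an initial network state
#'
#' Fixed nodes take their given values, clamped nodes their forced
#' values, and every remaining node is drawn i.i.d. uniform on \{0, 1\}
#' using R's RNG.
#'
#' @inheritParams async_successors
#' @param fixed named 0/1 vector of nodes with fixed initial values, or
#'   `NULL`.
#' @return A network state (named 0/1 vector).
#' @export
sample_initial_state <- function(model, fixed = NULL, clamps = NULL) {
  clamps <- validate_clamps(model, clamps)
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), model$nodes)
    if (length(unknown)) stop("fixed initial value for unknown node(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  st <- setNames(as.integer(runif(length(model$nodes)) < 0.5), model$nodes)
  if (length(fixed)) st[names(fixed)] <- as.integer(fixed)
  if (length(clamps)) st[names(clamps)] <- clamps
  st
}

init_fixed_vector <- function(model, config, clamps) {
  init <- rep(-1L, length(model$nodes))
  names(init) <- model$nodes
  if (!is.null(config$initial)) {
    unknown <- setdiff(names(config$initial), model$nodes)
    if (length(unknown)) stop("fixed initial value for unknown node(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    init[names(config$initial)] <- as.integer(config$initial)
  }
  if (length(clamps)) init[names(clamps)] <- clamps
  init
}

run_trajectories <- function(compiled, model, clamps, config) {
  clamps <- validate_clamps(model, clamps)
  init <- init_fixed_vector(model, config, clamps)
  res <- cpp_simulate(compiled$tokens,
                      match(names(clamps), model$nodes) - 1L,
                      unname(init),
                      config$n_trajectories, config$rate_up, config$rate_down,
                      config$max_time, as.double(config$seed))
  colnames(res$final) <- model$nodes
  res
}

#' Simulate one trajectory of the asynchronous dynamics
#'
#' Gillespie scheme on the asynchronous transition graph: the eligible
#' transitions of a state are its single-bit flips; each carries rate
#' `rate_up` or `rate_down`; the waiting time is exponential in the
#' total rate and the flip is chosen proportionally to its rate. The
#' walk stops on absorption in a stable state or when simulated time
#' exceeds `max_time`.
#'
#' @inheritParams async_successors
#' @param config a [sim_config()]; `n_trajectories` is ignored.
#' @return List with `final` (the end state), `end_time` and `absorbed`.
#' @export
simulate_trajectory <- function(model, clamps = NULL, config = sim_config()) {
  config$n_trajectories <- 1L
  compiled <- compile_boolean_model(model)
  res <- run_trajectories(compiled, model, clamps, config)
  list(final = setNames(res$final[1L, ], model$nodes),
       end_time = res$end_time[1L], absorbed = res$absorbed[1L])
}

#' Estimate phenotype probabilities by stochastic simulation
#'
#' Simulates `n_trajectories` independent trajectories and reports, for
#' each phenotype node, the fraction of trajectory endpoints with the
#' node ON. Because one endpoint can activate several phenotype nodes
#' the probabilities need not sum to one. `fraction_absorbed` flags
#' possible cyclic attractors: trajectories still moving at `max_time`
#' were cut off rather than absorbed.
#'
#' @inheritParams simulate_trajectory
#' @param nodes nodes to report; defaults to the six phenotype
#'   read-outs (intersected with the model's nodes).
#' @return A `phenotype_probabilities` object: list with `probabilities`
#'   (named vector), `se` (Monte-Carlo standard errors
#'   `sqrt(p (1 - p) / n)`), `n_trajectories`, `fraction_absorbed`, and
#'   the endpoint matrix `endpoints`.
#' @export
#' @examples
#' m <- load_metastasis_model()
#' pp <- estimate_phenotype_probabilities(m, c(NICD = 1, p53 = 0),
#'                                        sim_config(n_trajectories = 100))
#' pp$probabilities[["Metastasis"]]
estimate_phenotype_probabilities <- function(model, clamps = NULL,
                                             config = sim_config(),
                                             nodes = NULL) {
  if (is.null(nodes)) nodes <- intersect(phenotype_nodes(), model$nodes)
  compiled <- compile_boolean_model(model)
  res <- run_trajectories(compiled, model, clamps, config)
  p <- colMeans(res$final[, nodes, drop = FALSE])
  n <- config$n_trajectories
  structure(list(probabilities = p,
                 se = sqrt(p * (1 - p) / n),
                 n_trajectories = n,
                 fraction_absorbed = mean(res$absorbed),
                 endpoints = res$final),
            class = "phenotype_probabilities")
}

#' @export
print.phenotype_probabilities <- function(x, ...) {
  cat(sprintf("Phenotype probabilities (%d trajectories, %.1f%% absorbed)\n",
              x$n_trajectories, 100 * x$fraction_absorbed))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Distribution over phenotype combinations at trajectory endpoints
#'
#' Tabulates endpoint states by the combination of active phenotype
#' nodes (e.g. `"Apoptosis+CellCycleArrest"`; an all-OFF endpoint is
#' labelled `"none"`).
#'
#' @param pp a `phenotype_probabilities` object.
#' @param nodes phenotype nodes defining the combinations.
#' @return Named numeric vector of endpoint fractions summing to 1.
#' @export
phenotype_combination_distribution <- function(pp, nodes = phenotype_nodes()) {
  nodes <- intersect(nodes, colnames(pp$endpoints))
  labs <- apply(pp$endpoints[, nodes, drop = FALSE], 1L, function(b) {
    on <- nodes[b == 1L]
    if (length(on)) paste(on, collapse = "+") else "none"
  })
  tab <- table(labs)
  setNames(as.numeric(tab) / nrow(pp$endpoints), names(tab))
}

# --- exact absorption probabilities on small state spaces ------------------

#' Exact endpoint probabilities by linear absorption solve
#'
#' Builds the full asynchronous transition graph over the non-clamped
#' nodes (inputs are static dimensions of the state space) and solves
#' the absorbing-Markov-chain linear system for the probability of
#' ending in each stable state, starting from the uniform distribution
#' over initial states (restricted by `initial` fixes). Only feasible
#' when the number of free nodes is small; intended as the exact
#' counterpart of [estimate_phenotype_probabilities()] on desk-scale
#' models and as a deterministic fallback for heavily clamped ones.
#'
#' With equal rates the embedded jump chain picks uniformly among
#' eligible flips, so absorption probabilities do not depend on the rate
#' scale; unequal `rate_up` / `rate_down` weight the jump chain
#' accordingly.
#'
#' @inheritParams simulate_trajectory
#' @param initial named 0/1 vector fixing some nodes' initial values.
#' @param rate_up,rate_down flip rates (only their ratio matters).
#' @param max_free maximum number of free nodes accepted (state space
#'   `2^max_free`).
#' @return List with `node_probabilities` (probability of each node
#'   being ON at absorption), `absorption` (data frame of stable states
#'   and their absorption probabilities) and `states` (the stable-state
#'   matrix).
#' @export
exact_endpoint_probabilities <- function(model, clamps = NULL, initial = NULL,
                                         rate_up = 1, rate_down = 1,
                                         max_free = 14L) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("exact_endpoint_probabilities requires the Matrix package", call. = FALSE)
  }
  clamps <- validate_clamps(model, clamps)
  free <- setdiff(model$nodes, names(clamps))
  f <- length(free)
  if (f > max_free) {
    stop("state space too large for an exact solve: ", f, " free nodes", call. = FALSE)
  }
  flippable <- setdiff(setdiff(free, model$inputs), names(clamps))

  n_states <- 2^f
  bits <- matrix(0L, n_states, length(model$nodes),
                 dimnames = list(NULL, model$nodes))
  for (j in seq_len(f)) {
    bits[, free[j]] <- as.integer(bitwAnd(seq_len(n_states) - 1L, 2^(j - 1L)) > 0L)
  }
  if (length(clamps)) bits[, names(clamps)] <- rep(clamps, each = n_states)

  # rule values for every state via compiled tokens, one state at a time
  compiled <- compile_boolean_model(model)
  flip_idx <- match(flippable, model$nodes)
  succ <- vector("list", n_states)
  rates <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    st <- bits[s, ]
    to <- integer(0); rt <- numeric(0)
    for (nd in flippable) {
      v <- eval_rule_expr(model$rules[[nd]], st)
      if (v != st[[nd]]) {
        j <- match(nd, free)
        to <- c(to, s + if (v == 1L) 2^(j - 1L) else -2^(j - 1L))
        rt <- c(rt, if (v == 1L) rate_up else rate_down)
      }
    }
    succ[[s]] <- to
    rates[[s]] <- rt
  }
  absorbing <- vapply(succ, length, integer(1)) == 0L
  if (!any(absorbing)) stop("model has no stable state under these clamps", call. = FALSE)

  # initial distribution: uniform over free nodes, respecting `initial`
  pi0 <- rep(1 / n_states, n_states)
  if (!is.null(initial)) {
    unknown <- setdiff(names(initial), model$nodes)
    if (length(unknown)) stop("fixed initial value for unknown node(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    keep <- rep(TRUE, n_states)
    for (nd in names(initial)) {
      if (nd %in% names(clamps)) next
      keep <- keep & (bits[, nd] == as.integer(initial[[nd]]))
    }
    if (!any(keep)) stop("initial fixes are inconsistent with the clamps", call. = FALSE)
    pi0 <- ifelse(keep, 1, 0)
    pi0 <- pi0 / sum(pi0)
  }

  trans <- which(!absorbing)
  absb <- which(absorbing)
  pos_in_trans <- match(seq_len(n_states), trans)

  ii <- jj <- integer(0); xx <- numeric(0)
  ri <- ci <- integer(0); rx <- numeric(0)
  for (k in seq_along(trans)) {
    s <- trans[k]
    pr <- rates[[s]] / sum(rates[[s]])
    for (e in seq_along(succ[[s]])) {
      t2 <- succ[[s]][e]
      if (absorbing[t2]) {
        ri <- c(ri, k); ci <- c(ci, match(t2, absb)); rx <- c(rx, pr[e])
      } else {
        ii <- c(ii, k); jj <- c(jj, pos_in_trans[t2]); xx <- c(xx, pr[e])
      }
    }
  }
  nt <- length(trans)
  p_abs <- if (nt == 0L) {
    pi0[absb]
  } else {
    Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nt, nt))
    R <- Matrix::sparseMatrix(i = ri, j = ci, x = rx, dims = c(nt, length(absb)))
    B <- tryCatch(
      Matrix::solve(Matrix::Diagonal(nt) - Q, R),  # transient x absorbing
      error = function(e) stop("absorption solve failed (the model likely has ",
                               "cyclic attractors, so the endpoint law is not ",
                               "defined by absorption): ", conditionMessage(e),
                               call. = FALSE))
    as.numeric(pi0[trans] %*% B) + pi0[absb]
  }
  states <- bits[absb, , drop = FALSE]
  node_p <- as.numeric(p_abs %*% states)
  names(node_p) <- model$nodes
  list(node_probabilities = node_p,
       absorption = data.frame(state = seq_along(absb), probability = p_abs),
       states = states)
}
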
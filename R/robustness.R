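# Operator-swap robustness analysis: enumerate all model variants that
# differ from the wild type by one or two AND/OR flips, census their
# stable states, and measure distances to the wild-type states.
#
# Swap semantics: a swap flips one `&`/`|` operator token in the rule as
# written (negations and explicit parentheses untouched) and the rule is
# re-read under the usual precedence NOT > AND > OR. Around the flipped
# operator the rewritten rule therefore regroups by precedence: a `|`
# flipped inside an AND chain splits the chain, an `&` flipped inside an
# OR chain binds its two neighbouring operands.

#' List the binary operator sites of a model
#'
#' Operator sites are the `&` and `|` occurrences of each rule, indexed
#' 0-based in left-to-right reading of the rule as written.
#'
#' @inheritParams format_boolean_model
#' @return Data frame with columns `node`, `index` and `op`
#'   (`"AND"`/`"OR"`).
#' @export
operator_sites <- function(model) {
  compiled <- compile_boolean_model(model)
  out <- lapply(seq_along(compiled$nodes), function(i) {
    s <- compiled$sites[[i]]
    if (is.null(s) || length(s) == 0L) return(NULL)
    ops <- ifelse(compiled$tokens[[i]][s + 1L] == -2L, "AND", "OR")
    data.frame(node = compiled$nodes[i], index = seq_along(s) - 1L, op = ops)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(node = character(), index = integer(),
                                      op = character())
  rownames(res) <- NULL
  res
}

# flip the (k+1)-th operator character of a serialised rule (k 0-based)
swap_rule_text <- function(text, k) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  ops <- which(ch %in% c("&", "|"))
  if (k + 1L > length(ops)) stop("operator site index out of range", call. = FALSE)
  pos <- ops[k + 1L]
  ch[pos] <- if (ch[pos] == "&") "|" else "&"
  paste(ch, collapse = "")
}

# swapped rule expression of `node` with flips at the given 0-based sites
swapped_rule <- function(model, node, sites) {
  text <- format_rule(model$rules[[node]])
  for (k in sites) text <- swap_rule_text(text, k)
  parse_expr_tokens(tokenize_expr(text, 1L))
}

#' Enumerate all one- and two-swap operator variants of a model
#'
#' A variant flips AND to OR (or vice versa) at one operator site, at
#' two sites within the same rule, or at one site in each of two
#' distinct rules; the wild type itself is excluded and no variant is
#' listed twice.
#'
#' @inheritParams format_boolean_model
#' @return Data frame with columns `node1`, `site1`, `node2`, `site2`
#'   (`NA` for single swaps) and `class` (`"single"`, `"same_rule"`,
#'   `"cross_rule"`), in deterministic order.
#' @export
#' @examples
#' m <- load_metastasis_model()
#' nrow(enumerate_variants(m))  # 8001
enumerate_variants <- function(model) {
  sites <- operator_sites(model)
  singles <- data.frame(node1 = sites$node, site1 = sites$index,
                        node2 = NA_character_, site2 = NA_integer_,
                        class = "single")
  same <- do.call(rbind, lapply(split(sites, sites$node)[unique(sites$node)],
    function(g) {
      if (nrow(g) < 2L) return(NULL)
      cmb <- combn(g$index, 2L)
      data.frame(node1 = g$node[1], site1 = cmb[1, ],
                 node2 = g$node[1], site2 = cmb[2, ], class = "same_rule")
    }))
  rules <- unique(sites$node)
  cl <- list()
  for (a in seq_along(rules)) {
    for (b in seq_along(rules)) {
      if (b <= a) next
      g <- expand.grid(site1 = sites$index[sites$node == rules[a]],
                       site2 = sites$index[sites$node == rules[b]],
                       KEEP.OUT.ATTRS = FALSE)
      cl[[length(cl) + 1L]] <- data.frame(node1 = rules[a], site1 = g$site1,
                                          node2 = rules[b], site2 = g$site2,
                                          class = "cross_rule")
    }
  }
  cross_df <- if (length(cl)) do.call(rbind, cl) else NULL
  out <- rbind(singles, if (!is.null(same)) same, if (!is.null(cross_df)) cross_df)
  rownames(out) <- NULL
  out
}

#' Apply an operator-swap variant to a model
#'
#' @inheritParams format_boolean_model
#' @param variant one row of [enumerate_variants()] (or a list with the
#'   same fields).
#' @return The modified `boolean_model`.
#' @export
apply_variant <- function(model, variant) {
  if (!is.na(variant$node2) && identical(variant$node1, variant$node2)) {
    model$rules[[variant$node1]] <-
      swapped_rule(model, variant$node1, c(variant$site1, variant$site2))
  } else {
    model$rules[[variant$node1]] <- swapped_rule(model, variant$node1, variant$site1)
    if (!is.na(variant$node2)) {
      model$rules[[variant$node2]] <- swapped_rule(model, variant$node2, variant$site2)
    }
  }
  model
}

# cache of swapped-rule token vectors keyed by node and site(s); parsing
# happens once per distinct swapped rule, the census loop then only
# substitutes token vectors
swapped_token_cache <- function(model, compiled) {
  idx0 <- setNames(seq_along(model$nodes) - 1L, model$nodes)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(node, sites) {
    key <- paste(node, paste(sites, collapse = "_"), sep = "|")
    tok <- cache[[key]]
    if (is.null(tok)) {
      tok <- flatten_rule(swapped_rule(model, node, sites), idx0)$tokens
      cache[[key]] <- tok
    }
    tok
  }
}

variant_token_list <- function(compiled, get_tokens, node_idx, variant) {
  tokens <- compiled$tokens
  if (!is.na(variant$node2) && identical(variant$node1, variant$node2)) {
    tokens[[node_idx[[variant$node1]]]] <-
      get_tokens(variant$node1, c(variant$site1, variant$site2))
  } else {
    tokens[[node_idx[[variant$node1]]]] <- get_tokens(variant$node1, variant$site1)
    if (!is.na(variant$node2)) {
      tokens[[node_idx[[variant$node2]]]] <- get_tokens(variant$node2, variant$site2)
    }
  }
  tokens
}

#' Census of stable states across operator-swap variants
#'
#' Enumerates the stable states of every variant (inputs free), counts
#' occurrences with multiplicity across variants, pools the distinct
#' state vectors with their frequencies, and computes each distinct
#' state's Hamming distance to the nearest wild-type stable state
#' (over all nodes, inputs included).
#'
#' @inheritParams format_boolean_model
#' @param variants data frame from [enumerate_variants()]; defaults to
#'   all of them.
#' @param wildtype_states optional matrix of wild-type stable states
#'   (states in rows); defaults to enumerating them from `model`.
#' @return A `variant_census` list: `per_variant` (the variants table
#'   with a `n_stable` column), `total_occurrences`, `n_distinct`,
#'   `distinct` (data frame: packed state `key`, `frequency`,
#'   `dist_to_wt`), `distinct_states` (matrix), occurrence shares
#'   `share_wt` / `share_dist1` (fractions at distance 0 and 1) and
#'   `max_dist`.
#' @export
census_stable_states <- function(model, variants = enumerate_variants(model),
                                 wildtype_states = NULL) {
  compiled <- compile_boolean_model(model)
  n <- length(compiled$nodes)
  if (is.null(wildtype_states)) {
    wildtype_states <- stable_states_from_tokens(compiled, integer(), integer())
  }
  node_idx <- setNames(seq_along(model$nodes), model$nodes)
  get_tokens <- swapped_token_cache(model, compiled)

  pow <- 2^(seq_len(n) - 1L)
  n_stable <- integer(nrow(variants))
  keys <- vector("list", nrow(variants))
  key_states <- new.env(parent = emptyenv(), hash = TRUE)

  for (v in seq_len(nrow(variants))) {
    tokens <- variant_token_list(compiled, get_tokens, node_idx, variants[v, ])
    st <- cpp_stable_states(tokens, integer(), integer())
    n_stable[v] <- nrow(st)
    if (nrow(st)) {
      k <- as.numeric(st %*% pow)
      keys[[v]] <- k
      for (j in seq_len(nrow(st))) {
        kk <- sprintf("%.0f", k[j])
        if (is.null(key_states[[kk]])) key_states[[kk]] <- st[j, ]
      }
    }
  }

  all_keys <- unlist(keys, use.names = FALSE)
  freq <- table(sprintf("%.0f", all_keys))
  distinct_keys <- names(freq)
  distinct_states <- if (length(distinct_keys)) {
    do.call(rbind, lapply(distinct_keys, function(kk) key_states[[kk]]))
  } else {
    matrix(integer(), 0L, n)
  }
  colnames(distinct_states) <- compiled$nodes

  wt <- wildtype_states[, compiled$nodes, drop = FALSE]
  dist_to_wt <- if (nrow(distinct_states)) {
    apply(distinct_states, 1L, function(s) min(colSums(abs(t(wt) - s))))
  } else {
    integer()
  }

  total <- length(all_keys)
  occ <- as.numeric(freq)
  share_wt <- if (total) sum(occ[dist_to_wt == 0]) / total else 0
  share_dist1 <- if (total) sum(occ[dist_to_wt == 1]) / total else 0

  structure(list(per_variant = cbind(variants, n_stable = n_stable),
                 total_occurrences = total,
                 n_distinct = length(distinct_keys),
                 distinct = data.frame(key = distinct_keys,
                                       frequency = as.integer(freq),
                                       dist_to_wt = as.integer(dist_to_wt)),
                 distinct_states = distinct_states,
                 share_wt = share_wt,
                 share_dist1 = share_dist1,
                 max_dist = if (length(dist_to_wt)) as.integer(max(dist_to_wt))
                            else NA_integer_),
            class = "variant_census")
}

#' @export
print.variant_census <- function(x, ...) {
  cat(sprintf(paste0("Operator-swap census: %d variants, %d stable-state occurrences,\n",
                     "%d distinct states; %.0f%% at wild type, %.0f%% at distance 1, ",
                     "max distance %d\n"),
              nrow(x$per_variant), x$total_occurrences, x$n_distinct,
              100 * x$share_wt, 100 * x$share_dist1, x$max_dist))
  invisible(x)
}

#' Phenotype probabilities across a sample of variants
#'
#' Runs the stochastic simulation for a (sub)sample of operator-swap
#' variants and collects the per-variant phenotype probabilities, to
#' examine how concentrated they are around the wild-type values.
#'
#' @inheritParams census_stable_states
#' @param config a [sim_config()]; its seed drives both the subsampling
#'   and the per-variant simulations.
#' @param subsample number of variants to draw (without replacement);
#'   `NULL` uses all.
#' @param nodes phenotype nodes to report.
#' @return List with `probabilities` (variants x phenotypes matrix),
#'   `wildtype` (named vector) and the sampled `variants` table.
#' @export
phenotype_probability_sweep <- function(model, variants = enumerate_variants(model),
                                        config = sim_config(n_trajectories = 200),
                                        subsample = NULL, nodes = NULL) {
  if (is.null(nodes)) nodes <- intersect(phenotype_nodes(), model$nodes)
  if (!is.null(subsample) && subsample < nrow(variants)) {
    set.seed(config$seed)
    variants <- variants[sort(sample.int(nrow(variants), subsample)), , drop = FALSE]
  }
  compiled <- compile_boolean_model(model)
  node_idx <- setNames(seq_along(model$nodes), model$nodes)
  get_tokens <- swapped_token_cache(model, compiled)
  probs <- matrix(NA_real_, nrow(variants), length(nodes),
                  dimnames = list(NULL, nodes))
  for (v in seq_len(nrow(variants))) {
    vt <- compiled
    vt$tokens <- variant_token_list(compiled, get_tokens, node_idx, variants[v, ])
    cfg <- config
    cfg$seed <- (as.numeric(config$seed) + 7919 * v) %% 2^31
    res <- run_trajectories(vt, model, NULL, cfg)
    probs[v, ] <- colMeans(res$final[, nodes, drop = FALSE])
  }
  wtp <- estimate_phenotype_probabilities(model, NULL, config, nodes = nodes)
  list(probabilities = probs, wildtype = wtp$probabilities, variants = variants)
}
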
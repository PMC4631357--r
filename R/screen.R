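# Systematic single/double mutant screen, epistasis quantification,
# gene-pair classification and genetic-interaction network export.

#' Default mutatable genes of the metastasis model
#'
#' All nodes except the two free inputs and the six phenotype read-outs.
#'
#' @inheritParams format_boolean_model
#' @param include_inputs clamp the input nodes too.
#' @return Character vector of node names.
#' @export
mutatable_nodes <- function(model, include_inputs = FALSE) {
  excl <- intersect(phenotype_nodes(), model$nodes)
  if (!include_inputs) excl <- c(excl, model$inputs)
  setdiff(model$nodes, excl)
}

#' Enumerate all single and double mutants over a gene set
#'
#' For `n` genes this yields `2 n` single mutants (GoF and LoF per gene)
#' and `4 choose(n, 2)` double mutants (LoF/LoF, LoF/GoF, GoF/LoF,
#' GoF/GoF per unordered pair); no mutant clamps the same gene twice.
#'
#' @inheritParams format_boolean_model
#' @param genes model nodes to mutate.
#' @return Data frame with columns `gene1`, `dir1`, `gene2`, `dir2`
#'   (`NA` for singles) and `id`, in deterministic order.
#' @export
enumerate_mutants <- function(model, genes = mutatable_nodes(model)) {
  unknown <- setdiff(genes, model$nodes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  if (anyDuplicated(genes)) stop("duplicated gene in the mutant set", call. = FALSE)
  dirs <- c("LoF", "GoF")
  singles <- expand.grid(dir1 = dirs, gene1 = genes, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)[, c("gene1", "dir1")]
  singles$gene2 <- NA_character_
  singles$dir2 <- NA_character_
  doubles <- NULL
  if (length(genes) >= 2L) {
    prs <- combn(genes, 2L)
    doubles <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      g <- expand.grid(dir1 = dirs, dir2 = dirs, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
      data.frame(gene1 = prs[1, k], dir1 = g$dir1,
                 gene2 = prs[2, k], dir2 = g$dir2)
    }))
  }
  out <- rbind(singles, doubles)
  out$id <- ifelse(is.na(out$gene2),
                   paste0(out$gene1, "_", out$dir1),
                   paste0(out$gene1, "_", out$dir1, "__", out$gene2, "_", out$dir2))
  rownames(out) <- NULL
  out
}

#' Clamp set of a mutant
#'
#' @param mutant one row of [enumerate_mutants()] (or a list with fields
#'   `gene1`, `dir1` and optionally `gene2`, `dir2`).
#' @return Named 0/1 clamp vector (GoF = 1, LoF = 0).
#' @export
mutant_clamps <- function(mutant) {
  genes <- c(mutant$gene1, mutant$gene2)
  dirs <- c(mutant$dir1, mutant$dir2)
  keep <- !is.na(genes)
  genes <- genes[keep]; dirs <- dirs[keep]
  if (anyDuplicated(genes)) stop("a double mutant cannot clamp the same gene twice",
                                 call. = FALSE)
  setNames(as.integer(dirs == "GoF"), genes)
}

#' Epistasis score on the event of not having metastasis
#'
#' The multiplicative null model for not reaching the phenotype gives
#' `epsilon = (1 - p12) - (1 - p1) (1 - p2)`, where `p1`, `p2` are the
#' single-mutant phenotype probabilities and `p12` the double-mutant
#' one. Negative values are synergistic interactions (the two defects
#' amplify each other beyond the null), positive values alleviating
#' (masking) ones.
#'
#' @param p1,p2,p12 probabilities in `[0, 1]` (vectorised).
#' @return Epistasis score in `[-1, 1]`.
#' @export
#' @examples
#' compute_epistasis(0.2, 0.3, 0.9)  # -0.46
compute_epistasis <- function(p1, p2, p12) {
  for (p in list(p1, p2, p12)) {
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  (1 - p12) - (1 - p1) * (1 - p2)
}

#' Screen configuration
#'
#' @param phenotype target phenotype node.
#' @param synergy_threshold,alleviation_threshold epsilon cuts retained
#'   for the exported interaction network; values observed to fall in
#'   gaps of the epsilon distribution.
#' @param cancelled_tol probability below which a phenotype counts as
#'   cancelled when classifying gene pairs.
#' @param simulation a [sim_config()] shared by all mutants (each mutant
#'   derives its own substream from the master seed).
#' @return A `screen_config` list.
#' @export
screen_config <- function(phenotype = "Metastasis",
                          synergy_threshold = -0.2, alleviation_threshold = 0.3,
                          cancelled_tol = 0.05,
                          simulation = sim_config(n_trajectories = 200)) {
  stopifnot(synergy_threshold < 0, alleviation_threshold > 0)
  structure(list(phenotype = phenotype, synergy_threshold = synergy_threshold,
                 alleviation_threshold = alleviation_threshold,
                 cancelled_tol = cancelled_tol, simulation = simulation),
            class = "screen_config")
}

mutant_seed <- function(master, k) (as.numeric(master) + 104729 * k) %% 2^31

#' Run the systematic single/double mutant screen
#'
#' Estimates phenotype probabilities for the wild type and every single
#' and double mutant over `genes`, then computes the epistasis score of
#' all four direction combinations of every pair with respect to the
#' target phenotype.
#'
#' @inheritParams enumerate_mutants
#' @param config a [screen_config()].
#' @param nodes phenotype nodes reported in the mutant table.
#' @return A `mutant_screen` list: `mutants` (probability table, one row
#'   per mutant incl. wild type, one column per phenotype node plus
#'   `fraction_absorbed`), `epistasis` (one row per pair and direction
#'   combination: `p1`, `p2`, `p12`, `epsilon`), `combinations`
#'   (mutants x phenotype-combination endpoint fractions) and the
#'   config.
#' @export
run_screen <- function(model, genes = mutatable_nodes(model),
                       config = screen_config(), nodes = NULL) {
  if (is.null(nodes)) nodes <- intersect(phenotype_nodes(), model$nodes)
  mutants <- enumerate_mutants(model, genes)
  compiled <- compile_boolean_model(model)

  sim_one <- function(clamps, k) {
    cfg <- config$simulation
    cfg$seed <- mutant_seed(cfg$seed, k)
    res <- run_trajectories(compiled, model, clamps, cfg)
    res
  }

  ids <- c("wildtype", mutants$id)
  prob <- matrix(NA_real_, length(ids), length(nodes),
                 dimnames = list(ids, nodes))
  absorbed <- numeric(length(ids))
  comb_rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    clamps <- if (k == 1L) NULL else mutant_clamps(mutants[k - 1L, ])
    res <- tryCatch(sim_one(clamps, k), error = function(e) {
      warning("simulation failed for mutant ", ids[k], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    prob[k, ] <- colMeans(res$final[, nodes, drop = FALSE])
    absorbed[k] <- mean(res$absorbed)
    labs <- apply(res$final[, nodes, drop = FALSE], 1L, function(b) {
      on <- nodes[b == 1L]
      if (length(on)) paste(on, collapse = "+") else "none"
    })
    comb_rows[[k]] <- table(labs) / length(labs)
  }
  comb_labels <- sort(unique(unlist(lapply(comb_rows, names))))
  combinations <- matrix(0, length(ids), length(comb_labels),
                         dimnames = list(ids, comb_labels))
  for (k in seq_along(ids)) {
    if (!is.null(comb_rows[[k]])) {
      combinations[k, names(comb_rows[[k]])] <- as.numeric(comb_rows[[k]])
    }
  }

  target <- config$phenotype
  p_single <- function(gene, dir) prob[paste0(gene, "_", dir), target]
  doubles <- mutants[!is.na(mutants$gene2), , drop = FALSE]
  eps <- NULL
  if (nrow(doubles)) {
    eps <- data.frame(gene1 = doubles$gene1, dir1 = doubles$dir1,
                      gene2 = doubles$gene2, dir2 = doubles$dir2,
                      p1 = mapply(p_single, doubles$gene1, doubles$dir1),
                      p2 = mapply(p_single, doubles$gene2, doubles$dir2),
                      p12 = prob[doubles$id, target])
    eps$epsilon <- compute_epistasis(eps$p1, eps$p2, eps$p12)
    rownames(eps) <- NULL
  }

  structure(list(mutants = data.frame(id = ids, prob,
                                      fraction_absorbed = absorbed,
                                      check.names = FALSE),
                 epistasis = eps, combinations = combinations,
                 config = config),
            class = "mutant_screen")
}

#' Classify a gene pair from its four double-mutant probabilities
#'
#' Pattern-based classification of gene pairs by which of the four
#' direction combinations (LoF/LoF, LoF/GoF, GoF/LoF, GoF/GoF) cancel
#' the phenotype and which amplify it: `1a` (any GoF cancels, double
#' LoF amplifies), `1b` (any LoF cancels, double GoF amplifies), `2a`
#' (double GoF cancels; double LoF or a mixed synthetic-dosage
#' combination amplifies), `2b` (the mirror image), `3` (both
#' same-direction doubles cancel while a synthetic-dosage combination
#' amplifies). Pairs matching no pattern are `"other"`.
#'
#' @param p_ll,p_lg,p_gl,p_gg phenotype probabilities of the four
#'   direction combinations.
#' @param p_singles optional vector of the single-mutant probabilities;
#'   when given, "amplified" means exceeding their maximum.
#' @param cancelled_tol probability below which the phenotype counts as
#'   cancelled.
#' @return Character cluster id (`"1a"`, `"1b"`, `"2a"`, `"2b"`, `"3"`
#'   or `"other"`), plus an `amplitude` attribute (max - min of the four
#'   probabilities).
#' @export
classify_pair <- function(p_ll, p_lg, p_gl, p_gg, p_singles = NULL,
                          cancelled_tol = 0.05) {
  p <- c(ll = p_ll, lg = p_lg, gl = p_gl, gg = p_gg)
  cancelled <- p < cancelled_tol
  amp_min <- if (is.null(p_singles)) 0.5 else max(max(p_singles), cancelled_tol)
  amplified <- p > amp_min
  cls <- if (cancelled[["gg"]] && cancelled[["lg"]] && cancelled[["gl"]] &&
             amplified[["ll"]]) {
    "1a"
  } else if (cancelled[["ll"]] && cancelled[["lg"]] && cancelled[["gl"]] &&
             amplified[["gg"]]) {
    "1b"
  } else if (cancelled[["ll"]] && cancelled[["gg"]] &&
             (amplified[["lg"]] || amplified[["gl"]])) {
    "3"
  } else if (cancelled[["gg"]] &&
             (amplified[["ll"]] || amplified[["lg"]] || amplified[["gl"]])) {
    "2a"
  } else if (cancelled[["ll"]] &&
             (amplified[["gg"]] || amplified[["lg"]] || amplified[["gl"]])) {
    "2b"
  } else {
    "other"
  }
  structure(cls, amplitude = max(p) - min(p))
}

#' Gene-pair profiles and clusters from a screen
#'
#' @param screen a `mutant_screen`.
#' @return Data frame with one row per unordered gene pair: the four
#'   direction-combination probabilities, the amplitude (max - min) and
#'   the cluster id.
#' @export
gene_pair_profiles <- function(screen) {
  eps <- screen$epistasis
  if (is.null(eps)) return(NULL)
  target <- screen$config$phenotype
  key <- paste(eps$gene1, eps$gene2)
  prof <- lapply(split(eps, key), function(g) {
    pick <- function(d1, d2) g$p12[g$dir1 == d1 & g$dir2 == d2]
    singles <- c(g$p1[1], g$p2[1],
                 g$p1[g$dir1 == "GoF"][1], g$p2[g$dir2 == "GoF"][1])
    p_ll <- pick("LoF", "LoF"); p_lg <- pick("LoF", "GoF")
    p_gl <- pick("GoF", "LoF"); p_gg <- pick("GoF", "GoF")
    cls <- classify_pair(p_ll, p_lg, p_gl, p_gg,
                         p_singles = unique(c(g$p1, g$p2)),
                         cancelled_tol = screen$config$cancelled_tol)
    data.frame(gene1 = g$gene1[1], gene2 = g$gene2[1],
               p_ll = p_ll, p_lg = p_lg, p_gl = p_gl, p_gg = p_gg,
               amplitude = attr(cls, "amplitude"), cluster = as.character(cls))
  })
  out <- do.call(rbind, prof)
  rownames(out) <- NULL
  out[order(-out$amplitude), ]
}

#' Export the genetic interaction network
#'
#' Keeps the interactions passing the epsilon thresholds and builds a
#' network whose nodes are single mutants (sized by their own phenotype
#' probability) and whose edges are signed by interaction type (synergy
#' vs alleviation) and weighted by `|epsilon|`. Written as SIF and/or
#' GraphML.
#'
#' @param screen a `mutant_screen`.
#' @param sif,graphml optional output file paths.
#' @return The \pkg{igraph} graph, invisibly.
#' @export
export_interaction_network <- function(screen, sif = NULL, graphml = NULL) {
  cfg <- screen$config
  eps <- screen$epistasis
  keep <- eps[!is.na(eps$epsilon) &
              (eps$epsilon < cfg$synergy_threshold |
               eps$epsilon > cfg$alleviation_threshold), , drop = FALSE]
  from <- paste0(keep$gene1, "_", keep$dir1)
  to <- paste0(keep$gene2, "_", keep$dir2)
  vertices <- unique(c(from, to))
  size <- screen$mutants[match(vertices, screen$mutants$id), cfg$phenotype]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(vertices), name = vertices,
                            phenotype_probability = if (length(vertices)) size else numeric())
  if (nrow(keep)) {
    g <- igraph::add_edges(g, rbind(match(from, vertices), match(to, vertices)),
                           sign = ifelse(keep$epsilon < 0, "synergy", "alleviation"),
                           weight = abs(keep$epsilon), epsilon = keep$epsilon)
  }
  if (!is.null(sif)) {
    lines <- if (nrow(keep)) {
      paste(from, ifelse(keep$epsilon < 0, "synergy", "alleviation"), to)
    } else character()
    writeLines(lines, sif)
  }
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  invisible(g)
}

#' Exact census of fully metastatic synergies
#'
#' Finds the double mutants that make the metastatic phenotype certain
#' while neither single mutant does. "Certain" is operationalised
#' exactly: every stable state of the clamped model has the phenotype ON
#' (and at least one stable state exists), confirmed stochastically by
#' `n_confirm` trajectories that must all absorb in a phenotype-ON
#' state; a single mutant is "not certain" when it retains at least one
#' phenotype-OFF stable state.
#'
#' @inheritParams enumerate_mutants
#' @param phenotype target node.
#' @param n_confirm trajectories for the stochastic confirmation of each
#'   exact candidate.
#' @param seed seed for the confirmations.
#' @return Data frame of the qualifying double mutants with their single
#'   and double probabilities (exact 0/1 flags from the stable-state
#'   check, simulated `p12`).
#' @export
find_metastatic_synergies <- function(model, genes = mutatable_nodes(model),
                                      phenotype = "Metastasis",
                                      n_confirm = 1000, seed = 1) {
  compiled <- compile_boolean_model(model)
  node_idx <- setNames(seq_along(model$nodes), model$nodes)

  states_of <- function(clamps) {
    stable_states_from_tokens(compiled, node_idx[names(clamps)] - 1L, unname(clamps))
  }
  all_on <- function(st) nrow(st) > 0L && all(st[, phenotype] == 1L)
  any_off <- function(st) nrow(st) == 0L || any(st[, phenotype] == 0L)

  mutants <- enumerate_mutants(model, genes)
  singles <- mutants[is.na(mutants$gene2), , drop = FALSE]
  single_certain <- setNames(logical(nrow(singles)), singles$id)
  for (i in seq_len(nrow(singles))) {
    single_certain[i] <- all_on(states_of(mutant_clamps(singles[i, ])))
  }

  doubles <- mutants[!is.na(mutants$gene2), , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(doubles))) {
    mu <- doubles[i, ]
    id1 <- paste0(mu$gene1, "_", mu$dir1)
    id2 <- paste0(mu$gene2, "_", mu$dir2)
    if (single_certain[[id1]] || single_certain[[id2]]) next
    st <- states_of(mutant_clamps(mu))
    if (!all_on(st)) next
    # stochastic confirmation: all trajectories absorb in phenotype-ON states
    cfg <- sim_config(n_trajectories = n_confirm, seed = mutant_seed(seed, i))
    res <- run_trajectories(compiled, model, mutant_clamps(mu), cfg)
    p12 <- mean(res$final[, phenotype])
    if (all(res$absorbed) && p12 == 1) {
      hits[[length(hits) + 1L]] <- data.frame(mu[, c("gene1", "dir1", "gene2", "dir2", "id")],
                                              p12 = p12, n_stable = nrow(st))
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene1 = character(), dir1 = character(), gene2 = character(),
               dir2 = character(), id = character(), p12 = numeric(),
               n_stable = integer())
  rownames(out) <- NULL
  out
}

#' 2-D landscape coordinates of mutants
#'
#' Embeds mutants from their endpoint phenotype-combination
#' distributions by ordinary PCA: combination columns with mean
#' prevalence above `min_prevalence` are retained, centred and
#' projected on the first two principal axes (signs fixed so the
#' largest-magnitude loading of each axis is positive).
#'
#' @param combinations mutants x phenotype-combination matrix (e.g.
#'   `screen$combinations`).
#' @param min_prevalence minimum column mean retained.
#' @return Matrix with one row per mutant and columns `PC1`, `PC2`.
#' @export
mutant_landscape_coordinates <- function(combinations, min_prevalence = 0.01) {
  if (nrow(combinations) < 3L) stop("need at least 3 mutants", call. = FALSE)
  keep <- colMeans(combinations) > min_prevalence
  x <- combinations[, keep, drop = FALSE]
  if (ncol(x) < 2L || all(apply(x, 2L, stats::sd) == 0)) {
    # degenerate cloud: fall back to the raw first two columns
    out <- cbind(PC1 = x[, 1], PC2 = if (ncol(x) >= 2L) x[, 2] else 0)
    rownames(out) <- rownames(combinations)
    return(out)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) coords <- cbind(coords, 0)
  for (j in 1:2) {
    if (j <= ncol(pc$rotation)) {
      lead <- which.max(abs(pc$rotation[, j]))
      if (pc$rotation[lead, j] < 0) coords[, j] <- -coords[, j]
    }
  }
  colnames(coords) <- c("PC1", "PC2")
  coords
}
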
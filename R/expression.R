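# Expression matrices and the expression-based phenotype (EBP) score:
# matching binarized expression profiles to the model's stable states.

#' Construct an annotated expression matrix
#'
#' A thin container around a genes x samples numeric matrix (log-scale
#' expression assumed) with optional per-sample timepoint, replicate and
#' group annotations.
#'
#' @param values numeric matrix, genes in rows (rownames = gene
#'   symbols), samples in columns.
#' @param timepoint,replicate,group optional per-sample annotation
#'   vectors.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, timepoint = NULL, replicate = NULL, group = NULL) {
  if (is.null(rownames(values))) stop("values must have gene rownames", call. = FALSE)
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols", call. = FALSE)
  if (!all(is.finite(values))) stop("all expression values must be finite", call. = FALSE)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != ncol(values)) {
      stop(what, " must have one entry per sample", call. = FALSE)
    }
    x
  }
  structure(list(values = values,
                 timepoint = check_len(timepoint, "timepoint"),
                 replicate = check_len(replicate, "replicate"),
                 group = check_len(group, "group")),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$timepoint)) {
    cat("timepoints:", paste(unique(x$timepoint), collapse = ", "), "\n")
  }
  if (!is.null(x$group)) cat("groups:", paste(unique(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an expression matrix as TSV
#'
#' Genes in rows; the header carries `timepoint:replicate` annotations
#' when present (e.g. `T8:2`), otherwise plain sample names.
#'
#' @param expr an `expr_matrix`.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  header <- colnames(expr$values)
  if (!is.null(expr$timepoint)) {
    header <- paste0("T", expr$timepoint,
                     if (!is.null(expr$replicate)) paste0(":", expr$replicate) else "")
  }
  tab <- expr$values
  colnames(tab) <- header
  df <- data.frame(gene = rownames(tab), tab, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  hdr <- colnames(m)
  tp <- rep <- NULL
  if (all(grepl("^T[0-9.]+(\\:.+)?$", hdr))) {
    tp <- as.numeric(sub("^T([0-9.]+).*$", "\\1", hdr))
    if (all(grepl(":", hdr, fixed = TRUE))) rep <- sub("^[^:]*:", "", hdr)
    colnames(m) <- make.unique(hdr)
  }
  expr_matrix(m, timepoint = tp, replicate = rep)
}

#' Restrict an expression matrix to model-mappable genes
#'
#' Pairs model nodes with gene symbols via the node-to-gene map
#' (phenotype read-outs via their biomarkers), drops unmapped genes and
#' renames the retained rows to model node names.
#'
#' @param expr an `expr_matrix` with HUGO gene symbols as rownames.
#' @param model a `boolean_model`.
#' @param gene_map named character vector (node -> gene symbol);
#'   defaults to the bundled mapping including the biomarkers.
#' @return An `expr_matrix` whose rows are model node names, with the
#'   node/gene pairing in attribute `gene_mapping` and the dropped genes
#'   in attribute `dropped_genes`.
#' @export
map_genes_to_model <- function(expr, model = load_metastasis_model(),
                               gene_map = metastasis_gene_map()) {
  gene_map <- gene_map[names(gene_map) %in% model$nodes]
  found <- gene_map[gene_map %in% rownames(expr$values)]
  if (length(found) == 0L) {
    stop("no model-mappable genes in the expression matrix", call. = FALSE)
  }
  out <- expr
  out$values <- expr$values[unname(found), , drop = FALSE]
  rownames(out$values) <- names(found)
  attr(out, "gene_mapping") <- data.frame(node = names(found), gene = unname(found))
  attr(out, "dropped_genes") <- setdiff(rownames(expr$values), found)
  out
}

#' Average replicates within timepoints
#'
#' @param expr an `expr_matrix` with timepoint annotations.
#' @return An `expr_matrix` with one column per timepoint (arithmetic
#'   mean over available replicates, in increasing timepoint order).
#' @export
average_replicates <- function(expr) {
  if (is.null(expr$timepoint)) stop("expression matrix has no timepoint annotation",
                                    call. = FALSE)
  tps <- sort(unique(expr$timepoint))
  counts <- table(expr$timepoint)
  if (length(unique(counts)) > 1L) {
    warning("unequal replicate counts per timepoint; averaging over available replicates")
  }
  m <- vapply(tps, function(tp) {
    rowMeans(expr$values[, expr$timepoint == tp, drop = FALSE])
  }, numeric(nrow(expr$values)))
  m <- matrix(m, nrow = nrow(expr$values),
              dimnames = list(rownames(expr$values), paste0("T", tps)))
  expr_matrix(m, timepoint = tps)
}

# exact 1-D 2-means: minimise within-cluster sum of squares over all
# splits of the sorted values; returns the midpoint of the two centres
two_means_threshold <- function(v) {
  s <- sort(v)
  n <- length(s)
  best <- Inf
  thr <- NA_real_
  for (k in seq_len(n - 1L)) {
    m1 <- mean(s[1:k]); m2 <- mean(s[(k + 1L):n])
    ss <- sum((s[1:k] - m1)^2) + sum((s[(k + 1L):n] - m2)^2)
    if (ss < best - 1e-12) {
      best <- ss
      thr <- (m1 + m2) / 2
    }
  }
  thr
}

#' Binarize an expression series
#'
#' Assigns each gene a threshold and calls values at or above it ON.
#' With `method = "kmeans"` (default) the threshold is the midpoint of
#' the two cluster centres of an exact one-dimensional 2-means over the
#' gene's series; with `method = "quantile"` a single global threshold
#' (quantile `q` of the whole matrix) is used for all genes. Genes whose
#' series spans less than `min_range` are treated as flat and called
#' against the global threshold, giving the always-ON / always-OFF
#' flags; genes with both bits present are flagged dynamic.
#'
#' @param expr an `expr_matrix` (typically replicate-averaged, one
#'   column per timepoint).
#' @param method `"kmeans"` or `"quantile"`.
#' @param min_range minimum series range (log-expression units) for a
#'   gene to be considered dynamic rather than flat.
#' @param q quantile for the global threshold.
#' @return A `binarized_profile`: list with `bits` (genes x columns 0/1
#'   matrix), `flag` (per gene: `"dynamic"`, `"always_on"`,
#'   `"always_off"`) and `threshold` (per gene).
#' @export
binarize_expression <- function(expr, method = c("kmeans", "quantile"),
                                min_range = 1, q = 0.5) {
  method <- match.arg(method)
  v <- expr$values
  global_thr <- quantile(v, q)
  thr <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- diff(range(v[i, ]))
    thr[i] <- if (method == "quantile") {
      global_thr
    } else if (r < min_range) {
      global_thr
    } else {
      two_means_threshold(v[i, ])
    }
  }
  bits <- (v >= thr) + 0L
  flag <- apply(bits, 1L, function(b) {
    if (all(b == 1L)) "always_on" else if (all(b == 0L)) "always_off" else "dynamic"
  })
  structure(list(bits = bits, flag = flag, threshold = setNames(thr, rownames(v))),
            class = "binarized_profile")
}

#' Similarity matrix between a binarized profile and stable states
#'
#' For each timepoint and each stable state, an entry is 1 when the
#' gene's binarized bit equals the state's bit for the mapped node, and
#' 0 otherwise.
#'
#' @param binarized a `binarized_profile` whose rows are model node
#'   names (see [map_genes_to_model()]).
#' @param states node x state matrix of stable states (e.g.
#'   [metastasis_stable_states()]).
#' @param genes optional subset of rows to compare (e.g. only the
#'   dynamic genes).
#' @return List of genes x states 0/1 matrices, one per timepoint
#'   column.
#' @export
similarity_matrix <- function(binarized, states, genes = NULL) {
  rows <- rownames(binarized$bits)
  if (!is.null(genes)) rows <- intersect(rows, genes)
  rows <- intersect(rows, rownames(states))
  if (length(rows) == 0L) stop("no overlap between profile and stable-state nodes",
                               call. = FALSE)
  st <- states[rows, , drop = FALSE]
  lapply(setNames(colnames(binarized$bits), colnames(binarized$bits)), function(tp) {
    b <- binarized$bits[rows, tp]
    (st == b) + 0L
  })
}

#' EBP scores from a similarity matrix
#'
#' The expression-based phenotype (EBP) score of a stable state at a
#' timepoint is the number of compared genes whose binarized bit agrees
#' with the state; the highest-scoring states (ties preserved) identify
#' the phenotype closest to the sample.
#'
#' @param sim list of similarity matrices from [similarity_matrix()].
#' @param state_labels optional named character vector of phenotype
#'   labels per state (e.g. from [label_stable_state()] applied to each
#'   state column).
#' @return An `ebp_result`: list with `scores` (timepoints x states
#'   integer matrix), `n_genes`, `best` (list per timepoint of argmax
#'   state names) and `best_labels` when labels are given.
#' @export
ebp_score <- function(sim, state_labels = NULL) {
  scores <- t(vapply(sim, colSums, numeric(ncol(sim[[1]]))))
  storage.mode(scores) <- "integer"
  best <- apply(scores, 1L, function(r) colnames(scores)[r == max(r)],
                simplify = FALSE)
  res <- list(scores = scores, n_genes = nrow(sim[[1]]), best = best)
  if (!is.null(state_labels)) {
    res$best_labels <- lapply(best, function(b) unique(unname(state_labels[b])))
  }
  structure(res, class = "ebp_result")
}

#' @export
print.ebp_result <- function(x, ...) {
  cat("EBP scores (", x$n_genes, " genes compared)\n", sep = "")
  print(x$scores)
  for (tp in rownames(x$scores)) {
    cat(tp, ": best =", paste(x$best[[tp]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full EBP matching pipeline
#'
#' Chains gene mapping, replicate averaging, binarization, similarity
#' computation and EBP scoring of an expression time course against the
#' model's stable states.
#'
#' @param expr an `expr_matrix` with gene symbols and timepoint
#'   annotations.
#' @param model a `boolean_model`.
#' @param states node x state stable-state matrix.
#' @param genes genes (as model node names) to score; defaults to the
#'   mapped nodes of the eleven dynamically expressed genes. `NULL`
#'   scores every mapped gene with its constant or dynamic bit.
#' @param gene_map node -> gene symbol map.
#' @param ... passed to [binarize_expression()].
#' @return An `ebp_result` (see [ebp_score()]), with the binarized
#'   profile attached as attribute `binarized`.
#' @export
ebp_pipeline <- function(expr, model = load_metastasis_model(),
                         states = metastasis_stable_states(),
                         genes = names(metastasis_gene_map())[
                           metastasis_gene_map() %in% emt_dynamic_genes()],
                         gene_map = metastasis_gene_map(), ...) {
  mapped <- map_genes_to_model(expr, model, gene_map)
  avg <- if (!is.null(mapped$replicate)) average_replicates(mapped) else mapped
  bin <- binarize_expression(avg, ...)
  sim <- similarity_matrix(bin, states, genes = genes)
  labels <- vapply(colnames(states), function(s) {
    as.character(label_stable_state(setNames(states[, s], rownames(states))))
  }, character(1))
  res <- ebp_score(sim, state_labels = labels)
  attr(res, "binarized") <- bin
  res
}
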
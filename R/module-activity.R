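# Pathway/module activity scoring of expression cohorts and two-group
# differential activity testing.

#' Module activity scores by first-principal-component projection
#'
#' The activity of a module in a sample is the sample's contribution to
#' (projection onto) the first principal component computed across all
#' samples on the module's genes, after centring each gene. The sign of
#' each module's axis is fixed so that the score correlates positively
#' with the mean expression of the module genes (PCA leaves it
#' arbitrary otherwise). A single-gene module therefore scores as that
#' gene's centred expression.
#'
#' @param expr an `expr_matrix` (genes x samples).
#' @param modules named list of gene sets (gene symbols matching
#'   `rownames(expr$values)`).
#' @param standardise scale genes to unit variance before the PCA
#'   (default centring only).
#' @return An `activity_scores` matrix (samples x modules) with the
#'   per-module orientation record in attribute `orientation`; modules
#'   with no genes in the matrix are skipped with a message.
#' @export
activity_scores <- function(expr, modules, standardise = FALSE) {
  v <- expr$values
  out <- list()
  orientation <- numeric()
  for (mod in names(modules)) {
    genes <- intersect(modules[[mod]], rownames(v))
    if (length(genes) == 0L) {
      message("module '", mod, "' has no genes in the matrix; skipped")
      next
    }
    x <- t(v[genes, , drop = FALSE])  # samples x genes
    if (standardise) {
      sds <- apply(x, 2L, stats::sd)
      x <- x[, sds > 0, drop = FALSE]
      if (ncol(x) == 0L) {
        message("module '", mod, "' is constant; skipped")
        next
      }
    }
    pc <- prcomp(x, center = TRUE, scale. = standardise)
    score <- pc$x[, 1L]
    flip <- 1
    mean_expr <- rowMeans(x)
    if (stats::sd(mean_expr) > 0 && stats::cor(score, mean_expr) < 0) flip <- -1
    out[[mod]] <- flip * score
    orientation[mod] <- flip
  }
  if (length(out) == 0L) stop("no module has genes in the matrix", call. = FALSE)
  scores <- do.call(cbind, out)
  rownames(scores) <- colnames(v)
  attr(scores, "orientation") <- orientation
  class(scores) <- c("activity_scores", class(scores))
  scores
}

#' Differential module activity between two groups
#'
#' Welch's two-sample t-test (by default; `var.equal = TRUE` switches to
#' the pooled-variance test) of the activity score between the two
#' groups, per module.
#'
#' @param scores samples x modules matrix from [activity_scores()].
#' @param groups per-sample group labels (exactly two levels, e.g. M0 /
#'   M1), or a named vector matched by sample name.
#' @param alpha significance level.
#' @param var.equal use the pooled-variance t-test.
#' @return Data frame with one row per module: `t`, `p_value`, group
#'   means, and `significant` (`p_value < alpha`).
#' @export
differential_activity <- function(scores, groups, alpha = 0.05, var.equal = FALSE) {
  if (!is.null(names(groups))) groups <- groups[rownames(scores)]
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels", call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples", call. = FALSE)
  lv <- levels(groups)
  res <- lapply(colnames(scores), function(mod) {
    x <- scores[groups == lv[1], mod]
    y <- scores[groups == lv[2], mod]
    tt <- t.test(y, x, var.equal = var.equal)
    data.frame(module = mod, t = unname(tt$statistic), p_value = tt$p.value,
               mean_group0 = mean(x), mean_group1 = mean(y))
  })
  out <- do.call(rbind, res)
  names(out)[4:5] <- paste0("mean_", lv)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, character(1), 1))
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
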
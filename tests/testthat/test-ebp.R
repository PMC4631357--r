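make_expr <- function(values, ...) {
  expr_matrix(values, ...)
}

test_that("gene mapping renames rows to model nodes and drops the rest", {
  v <- matrix(rnorm(12), 4, 3,
              dimnames = list(c("CDH1", "CDH2", "CASP9", "NOTAGENE"), NULL))
  mapped <- map_genes_to_model(make_expr(v))
  expect_setequal(rownames(mapped$values), c("CDH1", "CDH2", "Apoptosis"))
  expect_identical(unname(mapped$values["Apoptosis", ]), unname(v["CASP9", ]))
  expect_true("NOTAGENE" %in% attr(mapped, "dropped_genes"))

  vim <- matrix(1, 1, 2, dimnames = list("VIM", NULL))
  expect_identical(rownames(map_genes_to_model(make_expr(vim))$values), "VIM")
  none <- matrix(1, 1, 2, dimnames = list("NOTAGENE", NULL))
  expect_error(map_genes_to_model(make_expr(none)), "no model-mappable genes")
})

test_that("replicate averaging is the per-timepoint arithmetic mean", {
  v <- matrix(c(1, 2, 3, 10, 10, 13), 1, 6,
              dimnames = list("CDH1", NULL))
  e <- make_expr(v, timepoint = c(0, 0, 0, 8, 8, 8), replicate = rep(1:3, 2))
  avg <- average_replicates(e)
  expect_identical(unname(avg$values[1, ]), c(2, 11))
  single <- make_expr(v[, 1, drop = FALSE], timepoint = 0, replicate = 1)
  expect_identical(unname(average_replicates(single)$values[1, 1]), 1)
  uneq <- make_expr(v[, 1:5, drop = FALSE], timepoint = c(0, 0, 0, 8, 8),
                    replicate = c(1:3, 1:2))
  expect_warning(avg2 <- average_replicates(uneq), "unequal replicate")
  expect_identical(unname(avg2$values[1, ]), c(2, 10))
})

test_that("two-means binarization thresholds at the cluster midpoint", {
  v <- rbind(g1 = c(1, 1, 9, 9), g2 = c(8, 8, 8, 8), g3 = c(1, 1, 1, 1))
  e <- make_expr(v, timepoint = c(0, 8, 24, 72))
  b <- binarize_expression(e)
  expect_identical(unname(b$bits["g1", ]), c(0L, 0L, 1L, 1L))
  expect_equal(unname(b$threshold[["g1"]]), 5)
  # flat genes are called against the global threshold (here the median)
  expect_identical(unname(b$flag), c("dynamic", "always_on", "always_off"))
})

test_that("quantile binarization is invariant to monotone transforms", {
  set.seed(7)
  v <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("g", 1:8), NULL))
  e1 <- make_expr(v, timepoint = 1:5)
  e2 <- make_expr(2 * v + 3, timepoint = 1:5)
  b1 <- binarize_expression(e1, method = "quantile")
  b2 <- binarize_expression(e2, method = "quantile")
  expect_identical(b1$bits, b2$bits)
})

test_that("the similarity matrix marks bitwise agreement", {
  states <- cbind(S1 = c(1L, 0L, 1L), S2 = c(0L, 0L, 0L))
  rownames(states) <- c("a", "b", "c")
  bin <- structure(list(bits = cbind(T0 = c(a = 1L, b = 1L, c = 1L)),
                        flag = c(a = "dynamic", b = "dynamic", c = "dynamic")),
                   class = "binarized_profile")
  sim <- similarity_matrix(bin, states)
  expect_identical(unname(sim$T0[, "S1"]), c(1L, 0L, 1L))
  expect_identical(unname(sim$T0[, "S2"]), c(0L, 0L, 0L))
  sc <- ebp_score(sim)
  expect_identical(unname(sc$scores[1, ]), c(2L, 0L))
  expect_identical(sc$best$T0, "S1")
})

test_that("EBP identities: perfect match, complement, and their sum", {
  m <- load_metastasis_model()
  fix <- metastasis_stable_states()
  map <- metastasis_gene_map()
  nodes <- names(map)
  profile <- fix[nodes, "M1"]
  mk_bin <- function(bits) {
    structure(list(bits = cbind(T0 = bits),
                   flag = setNames(rep("dynamic", length(bits)), nodes)),
              class = "binarized_profile")
  }
  sc <- ebp_score(similarity_matrix(mk_bin(profile), fix))
  expect_identical(unname(sc$scores[1, "M1"]), length(nodes))
  # states whose restriction differs from M1 score strictly less
  restr <- apply(fix[nodes, ], 2, paste, collapse = "")
  same_as_m1 <- names(restr)[restr == restr[["M1"]]]
  expect_true(all(sc$scores[1, setdiff(colnames(fix), same_as_m1)] < length(nodes)))

  comp <- ebp_score(similarity_matrix(mk_bin(1L - profile), fix))
  expect_identical(unname(comp$scores[1, "M1"]), 0L)
  expect_identical(sc$scores[1, ] + comp$scores[1, ],
                   setNames(rep(length(nodes), ncol(fix)), colnames(fix)))
})

test_that("the full pipeline tracks the EMT induction from epithelial to metastatic", {
  tc <- generate_timecourse()
  res <- ebp_pipeline(tc$expr)
  met_states <- c("M1", "M2")
  first <- res$best[[1]]
  last <- res$best[[length(res$best)]]
  expect_length(intersect(first, met_states), 0L)
  expect_true(all(last %in% met_states))
  # the best metastatic score rises monotonically through the course
  met_score <- apply(res$scores[, met_states, drop = FALSE], 1L, max)
  expect_true(all(diff(met_score) >= 0))
  expect_true(all(vapply(res$best_labels, length, integer(1)) >= 1L))
})
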
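test_that("single-gene and duplicated-gene modules score as the centred profile", {
  set.seed(5)
  v <- matrix(rnorm(30, mean = 6), 3, 10,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:10)))
  e <- expr_matrix(v)
  sc <- activity_scores(e, list(one = "g1"))
  expect_equal(unname(sc[, "one"]), unname(v["g1", ] - mean(v["g1", ])))

  # two perfectly correlated genes: score proportional to the common profile
  v2 <- rbind(a = v["g1", ], b = 2 * v["g1", ] + 1)
  sc2 <- activity_scores(expr_matrix(v2), list(mod = c("a", "b")))
  centred <- v["g1", ] - mean(v["g1", ])
  expect_equal(abs(stats::cor(sc2[, "mod"], centred)), 1, tolerance = 1e-10)
  expect_gt(stats::cor(sc2[, "mod"], centred), 0)  # orientation follows expression
})

test_that("PC1 scores reproduce the closed-form 2x2 eigenvector projection", {
  set.seed(11)
  v <- matrix(rnorm(40), 2, 20, dimnames = list(c("a", "b"), NULL))
  v["b", ] <- 0.6 * v["a", ] + 0.4 * v["b", ]
  sc <- activity_scores(expr_matrix(v), list(m = c("a", "b")))
  x <- scale(t(v), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))$vectors[, 1]
  expect_equal(abs(unname(sc[, "m"])), abs(unname(x %*% ev)[, 1]), tolerance = 1e-8)
})

test_that("scores are centred, shift-invariant and scale-equivariant", {
  set.seed(3)
  v <- matrix(rnorm(50, 8), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  mods <- list(m = c("g1", "g2", "g3"))
  sc <- activity_scores(expr_matrix(v), mods)
  expect_lt(abs(mean(sc[, "m"])), 1e-10)
  v_shift <- v
  v_shift["g2", ] <- v["g2", ] + 100   # constant per-gene shift
  expect_equal(activity_scores(expr_matrix(v_shift), mods)[, "m"], sc[, "m"])
  expect_equal(activity_scores(expr_matrix(3 * v), mods)[, "m"], 3 * sc[, "m"])
})

test_that("differential activity flags the planted shifts with correct signs", {
  co <- generate_cohort()   # 88 vs 17, AKT2 +1 SD, miRNA -1 SD
  sc <- activity_scores(co$expr, co$modules)
  da <- differential_activity(sc, co$expr$group)
  akt2 <- da[da$module == "AKT2", ]
  mirna <- da[da$module == "miRNA", ]
  expect_true(akt2$significant)
  expect_gt(akt2$t, 0)
  expect_true(mirna$significant)
  expect_lt(mirna$t, 0)
  expect_error(differential_activity(sc, rep("M0", nrow(sc))), "two levels")
})

test_that("power exceeds 0.9 for a 1-SD ten-gene module shift at n = 50 vs 50", {
  hits <- vapply(1:200, function(i) {
    co <- generate_cohort(cohort_spec(n_group0 = 50, n_group1 = 50,
                                      effects = c(AKT2 = 1), n_background = 0,
                                      seed = 1000 + i),
                          modules = "AKT2")
    sc <- activity_scores(co$expr, co$modules)
    differential_activity(sc, co$expr$group)$significant
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("null cohorts produce uniform p-values and nominal error rates", {
  ps <- vapply(1:150, function(i) {
    co <- generate_cohort(cohort_spec(n_group0 = 20, n_group1 = 20,
                                      effects = c(AKT2 = 0), n_background = 0,
                                      seed = 5000 + i),
                          modules = "AKT2")
    sc <- activity_scores(co$expr, co$modules)
    differential_activity(sc, co$expr$group)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("gene sets round trip through GMT", {
  sets <- list(alpha = c("g1", "g2"), beta = c("g3"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})
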
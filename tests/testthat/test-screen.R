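test_that("mutant enumeration has the right combinatorics", {
  m <- load_metastasis_model()
  mm <- enumerate_mutants(m, c("NICD", "p53"))
  expect_identical(sum(is.na(mm$gene2)), 4L)
  expect_identical(sum(!is.na(mm$gene2)), 4L)
  expect_identical(sum(mm$gene1 == "NICD" & mm$dir1 == "GoF" &
                       mm$gene2 == "p53" & mm$dir2 == "LoF", na.rm = TRUE), 1L)

  g26 <- mutatable_nodes(m, include_inputs = TRUE)
  expect_length(g26, 26L)
  all26 <- enumerate_mutants(m, g26)
  expect_identical(sum(is.na(all26$gene2)), 52L)
  expect_identical(sum(!is.na(all26$gene2)), 1300L)
  expect_false(anyDuplicated(all26$id) > 0L)

  expect_length(mutatable_nodes(m), 24L)
  expect_error(enumerate_mutants(m, c("NICD", "NICD")), "duplicated")
  expect_error(mutant_clamps(list(gene1 = "p53", dir1 = "GoF",
                                  gene2 = "p53", dir2 = "LoF")), "twice")
})

test_that("epsilon arithmetic follows the multiplicative null model", {
  expect_identical(compute_epistasis(0, 0, 0), 0)
  expect_identical(compute_epistasis(0, 0, 1), -1)
  expect_equal(compute_epistasis(0.2, 0.3, 0.9), -0.46)
  # symmetry and the exact-null identity
  for (i in 1:20) {
    p <- runif(3)
    expect_identical(compute_epistasis(p[1], p[2], p[3]),
                     compute_epistasis(p[2], p[1], p[3]))
    null12 <- 1 - (1 - p[1]) * (1 - p[2])
    expect_equal(compute_epistasis(p[1], p[2], null12), 0)
  }
  expect_error(compute_epistasis(-0.1, 0, 0), "\\[0, 1\\]")
  expect_error(compute_epistasis(0, 1.2, 0), "\\[0, 1\\]")
})

test_that("gene pairs classify by their cancel/amplify pattern", {
  expect_identical(as.character(classify_pair(0, 1, 0, 0)), "3")
  expect_identical(as.character(classify_pair(0.3, 0.3, 0.3, 0.3)), "other")
  expect_identical(attr(classify_pair(0.3, 0.3, 0.3, 0.3), "amplitude"), 0)
  expect_identical(as.character(classify_pair(0.9, 0.5, 0.5, 0)), "2a")
  expect_identical(as.character(classify_pair(0.9, 0, 0, 0)), "1a")
  expect_identical(as.character(classify_pair(0, 0, 0, 0.9)), "1b")
  expect_identical(as.character(classify_pair(0, 0.6, 0, 0.9)), "2b")
  # amplification relative to the singles when given
  expect_identical(as.character(classify_pair(0, 0.4, 0, 0,
                                              p_singles = c(0.5, 0.2))), "other")
})

test_that("a small screen is reproducible and finds the NICD/p53 synergy", {
  m <- load_metastasis_model()
  cfg <- screen_config(simulation = sim_config(n_trajectories = 120, seed = 2))
  s1 <- run_screen(m, c("NICD", "p53"), cfg)
  s2 <- run_screen(m, c("NICD", "p53"), cfg)
  expect_identical(s1$mutants, s2$mutants)
  expect_identical(s1$epistasis, s2$epistasis)

  rec <- s1$epistasis[s1$epistasis$dir1 == "GoF" & s1$epistasis$dir2 == "LoF", ]
  expect_identical(rec$p12, 1)
  expect_lt(rec$epsilon, 0)
  # a clamp with no path to the target leaves the double equal to the
  # other single (the Apoptosis node feeds into no other rule)
  s3 <- run_screen(m, c("NICD", "Apoptosis"), cfg)
  inert <- s3$epistasis[s3$epistasis$gene2 == "Apoptosis", ]
  expect_true(all(abs(inert$p12 - inert$p1) < 0.1))
})

test_that("interaction networks keep only threshold-passing edges", {
  screen <- list(
    mutants = data.frame(id = c("A_GoF", "B_LoF", "C_GoF"),
                         Metastasis = c(0.5, 0.1, 0.9)),
    epistasis = data.frame(gene1 = c("A", "A", "B"), dir1 = c("GoF", "GoF", "LoF"),
                           gene2 = c("B", "C", "C"), dir2 = c("LoF", "GoF", "GoF"),
                           p1 = 0.5, p2 = 0.1, p12 = 0.9,
                           epsilon = c(-0.5, 0.1, 0.4)),
    config = screen_config())
  class(screen) <- "mutant_screen"
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  g <- export_interaction_network(screen, sif = sif, graphml = gml)
  expect_identical(igraph::ecount(g), 2)         # -0.5 and 0.4 pass, 0.1 does not
  expect_setequal(igraph::E(g)$sign, c("synergy", "alleviation"))
  expect_equal(sort(igraph::E(g)$weight), c(0.4, 0.5))
  lines <- readLines(sif)
  expect_length(lines, 2L)
  expect_true(any(grepl("A_GoF synergy B_LoF", lines)))
  expect_true(file.exists(gml))
})

test_that("the exact synergy census finds the four reference pairs", {
  m <- load_metastasis_model()
  syn <- find_metastatic_synergies(m, c("NICD", "p53", "p73", "SNAI2", "AKT2"),
                                   n_confirm = 300, seed = 4)
  expect_setequal(syn$id, c("NICD_GoF__p53_LoF", "NICD_GoF__p73_GoF",
                            "NICD_GoF__SNAI2_GoF", "NICD_GoF__AKT2_GoF"))
  expect_true(all(syn$p12 == 1))
})

test_that("mutant landscape coordinates are deterministic and PCA-faithful", {
  x <- rbind(a = c(0.5, 0.1, 0.0), b = c(0.5, 0.1, 0.0), c = c(0.1, 0.8, 0.1),
             d = c(0.2, 0.2, 0.6))
  colnames(x) <- c("P1", "P2", "P3")
  co <- mutant_landscape_coordinates(x, min_prevalence = 0)
  expect_identical(co["a", ], co["b", ])   # identical profiles coincide
  # against a closed-form eigendecomposition of the covariance matrix
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))
  proj <- xc %*% ev$vectors[, 1:2]
  expect_equal(abs(unname(co)), abs(unname(proj)), tolerance = 1e-8)
  expect_error(mutant_landscape_coordinates(x[1:2, , drop = FALSE]), "at least 3")
})
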
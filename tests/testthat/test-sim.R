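test_that("initial-state sampling honours fixed nodes, clamps and uniformity", {
  m <- load_metastasis_model()
  fix <- metastasis_stable_states()
  hs <- setNames(fix[, "HS"], rownames(fix))
  set.seed(1)
  for (i in 1:5) expect_identical(sample_initial_state(m, fixed = hs)[names(hs)], hs)

  set.seed(2)
  draws <- replicate(10000, sample_initial_state(m,
    fixed = c(ECMicroenv = 1, GF = 1, TGFbeta = 1))["CDH1"])
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  set.seed(3)
  for (i in 1:20) {
    s <- sample_initial_state(m, fixed = c(ECMicroenv = 1, GF = 1, TGFbeta = 1))
    expect_identical(unname(s[c("ECMicroenv", "GF", "TGFbeta")]), c(1L, 1L, 1L))
  }
  expect_error(sample_initial_state(m, fixed = c(NoNode = 1)), "unknown node")
})

test_that("trajectories absorb immediately at stable states and are seed-reproducible", {
  m <- load_metastasis_model()
  fix <- metastasis_stable_states()
  hs <- setNames(fix[, "HS"], rownames(fix))
  tr <- simulate_trajectory(m, config = sim_config(seed = 5, initial = hs))
  expect_true(tr$absorbed)
  expect_identical(tr$end_time, 0)
  expect_identical(tr$final[names(hs)], hs)

  t1 <- simulate_trajectory(m, config = sim_config(seed = 42))
  t2 <- simulate_trajectory(m, config = sim_config(seed = 42))
  expect_identical(t1, t2)
})

test_that("the NICD-GoF/p53-LoF double mutant always ends metastatic", {
  m <- load_metastasis_model()
  tr <- simulate_trajectory(m, c(NICD = 1, p53 = 0), sim_config(seed = 9))
  expect_true(tr$absorbed)
  expect_identical(unname(tr$final["Metastasis"]), 1L)
})

test_that("clamped nodes have degenerate phenotype probabilities", {
  m <- load_metastasis_model()
  pp <- estimate_phenotype_probabilities(m, c(Migration = 1, Apoptosis = 0),
                                         sim_config(n_trajectories = 200, seed = 3),
                                         nodes = c("Migration", "Apoptosis"))
  expect_identical(unname(pp$probabilities), c(1, 0))
  expect_identical(unname(pp$se), c(0, 0))
})

test_that("endpoint states satisfy the phenotype implications", {
  m <- load_metastasis_model()
  pp <- estimate_phenotype_probabilities(m, config = sim_config(n_trajectories = 500,
                                                                seed = 17))
  ends <- pp$endpoints
  expect_true(all(ends[ends[, "Apoptosis"] == 1L, "CellCycleArrest"] == 1L))
  met <- ends[ends[, "Metastasis"] == 1L, , drop = FALSE]
  expect_true(all(met[, c("EMT", "Invasion", "Migration")] == 1L))
})

test_that("trajectory substreams are stable when n_trajectories grows", {
  m <- load_metastasis_model()
  p100 <- estimate_phenotype_probabilities(m, config = sim_config(n_trajectories = 100,
                                                                  seed = 11))
  p200 <- estimate_phenotype_probabilities(m, config = sim_config(n_trajectories = 200,
                                                                  seed = 11))
  expect_identical(p100$endpoints, p200$endpoints[1:100, ])
})

test_that("exact absorption probabilities match a hand-solved chain", {
  # x = x | y, y = x & y: stable states 00, 10, 11; the only transient
  # state 01 splits 1/2 to 11 (flip x) and 1/2 to 00 (flip y). From a
  # uniform start: P(x ON) = 1/4 + 1/8 + 1/4 = 5/8, P(y ON) = 3/8.
  toy <- parse_boolean_model(c("x = x | y", "y = x & y"))
  ex <- exact_endpoint_probabilities(toy)
  expect_equal(unname(ex$node_probabilities[c("x", "y")]), c(5 / 8, 3 / 8))
  expect_identical(nrow(ex$states), 3L)
})

test_that("simulation agrees with the exact absorption solve within 3 MC SE", {
  checked <- 0L
  for (seed in 1:12) {
    m <- generate_random_model(7, 3, seed = seed, n_inputs = seed %% 2L)
    ex <- tryCatch(exact_endpoint_probabilities(m), error = function(e) NULL)
    if (is.null(ex)) next   # cyclic attractors: endpoint law not absorption-defined
    n <- 2000L
    pp <- estimate_phenotype_probabilities(m, config = sim_config(n_trajectories = n,
                                                                  seed = seed),
                                           nodes = m$nodes)
    if (pp$fraction_absorbed < 1) next
    p <- pmin(pmax(ex$node_probabilities[m$nodes], 0), 1)
    se <- pmax(sqrt(p * (1 - p) / n), 1e-3)
    expect_true(all(abs(pp$probabilities - p) <= 3 * se))
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})

test_that("phenotype-combination distributions sum to one", {
  m <- load_metastasis_model()
  pp <- estimate_phenotype_probabilities(m, config = sim_config(n_trajectories = 300,
                                                                seed = 23))
  d <- phenotype_combination_distribution(pp)
  expect_equal(sum(d), 1)
  expect_true(all(d >= 0))
})
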
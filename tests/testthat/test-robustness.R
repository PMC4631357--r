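test_that("operator-site census of the bundled model is consistent", {
  m <- load_metastasis_model()
  sites <- operator_sites(m)
  expect_identical(nrow(sites), 126L)
  expect_false("Metastasis" %in% sites$node)       # single-variable rule
  expect_identical(sum(sites$node == "CDH2"), 0L)
  # per-rule counts must reproduce the three variant-class sizes
  k <- table(sites$node)
  v <- enumerate_variants(m)
  expect_identical(sum(v$class == "single"), 126L)
  expect_identical(sum(v$class == "same_rule"), as.integer(sum(choose(k, 2))))
  expect_identical(sum(v$class == "cross_rule"),
                   as.integer((sum(k)^2 - sum(k^2)) / 2))
  expect_identical(nrow(v), 8001L)
  expect_false(anyDuplicated(v[, 1:4]) > 0L)
})

test_that("models with at most one operator per rule have no same-rule pairs", {
  m <- parse_boolean_model(c("input a", "input b", "x = a & b", "y = !x | a"))
  v <- enumerate_variants(m)
  expect_identical(sum(v$class == "same_rule"), 0L)
  expect_identical(nrow(v), 3L)   # 2 singles + 1 cross pair
})

test_that("a swap flips the operator in the rule text and re-binds by precedence", {
  m <- parse_boolean_model(c("input a", "input b", "input c", "input d",
                             "x = a | b | c | d", "y = a & b & c"))
  # flipping the middle OR binds only its two neighbours: a | (b & c) | d
  v1 <- apply_variant(m, list(node1 = "x", site1 = 1L,
                              node2 = NA_character_, site2 = NA_integer_))
  expect_identical(boolmet:::format_rule(v1$rules[["x"]]), "a | b & c | d")
  # flipping the last AND splits the conjunction: (a & b) | c
  v2 <- apply_variant(m, list(node1 = "y", site1 = 1L,
                              node2 = NA_character_, site2 = NA_integer_))
  expect_identical(boolmet:::format_rule(v2$rules[["y"]]), "a & b | c")
  # two swaps in the same rule are applied together
  v3 <- apply_variant(m, list(node1 = "x", site1 = 0L, node2 = "x", site2 = 2L))
  expect_identical(boolmet:::format_rule(v3$rules[["x"]]), "a & b | c & d")
})

test_that("the token-level census agrees with apply_variant plus brute force", {
  for (seed in c(3, 8, 21)) {
    m <- generate_random_model(7, 3, seed = seed, n_inputs = 1)
    v <- enumerate_variants(m)
    if (nrow(v) == 0L) next
    cen <- census_stable_states(m, v)
    slow_total <- 0L
    slow_keys <- character()
    for (i in seq_len(nrow(v))) {
      st <- brute_stable_states(apply_variant(m, v[i, ]))
      slow_total <- slow_total + nrow(st)
      slow_keys <- c(slow_keys, state_keys(st))
    }
    expect_identical(cen$total_occurrences, slow_total)
    expect_identical(cen$n_distinct, length(unique(slow_keys)))
    expect_identical(unname(cen$per_variant$n_stable),
                     vapply(seq_len(nrow(v)), function(i) {
                       nrow(brute_stable_states(apply_variant(m, v[i, ])))
                     }, integer(1)))
  }
})

test_that("census totals are invariant under variant order", {
  m <- generate_random_model(6, 3, seed = 13)
  v <- enumerate_variants(m)
  c1 <- census_stable_states(m, v)
  set.seed(1)
  c2 <- census_stable_states(m, v[sample.int(nrow(v)), ])
  expect_identical(c1$total_occurrences, c2$total_occurrences)
  expect_identical(c1$n_distinct, c2$n_distinct)
  expect_identical(c1$distinct, c2$distinct)
  expect_identical(c1$max_dist, c2$max_dist)
})

test_that("wild-type states sit at distance zero in their own census", {
  m <- generate_random_model(6, 2, seed = 4)
  cen <- census_stable_states(m)
  wt <- enumerate_stable_states(m)
  wt_keys <- state_keys(wt)
  got <- state_keys(cen$distinct_states[cen$distinct$dist_to_wt == 0L, ,
                                        drop = FALSE])
  expect_true(all(got %in% wt_keys))
})

test_that("phenotype sweeps are deterministic and sized by the subsample", {
  m <- load_metastasis_model()
  cfg <- sim_config(n_trajectories = 60, seed = 31)
  s1 <- phenotype_probability_sweep(m, config = cfg, subsample = 5)
  s2 <- phenotype_probability_sweep(m, config = cfg, subsample = 5)
  expect_identical(s1$probabilities, s2$probabilities)
  expect_identical(nrow(s1$probabilities), 5L)
  expect_true(all(s1$probabilities >= 0 & s1$probabilities <= 1))
})
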
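test_that("the noisy oracle labels pairs consistently and flips the stated count", {
  cov <- random_cover(40, 5, seed = 2)
  ids <- unique(unlist(cov))
  oracle <- make_noisy_oracle(cov, rate = 0.1, seed = 3)
  pairs <- t(utils::combn(ids[1:20], 2))
  cs <- oracle(pairs)
  n_min <- min(sum(cs$observed == "ML"), sum(cs$observed == "CL"))
  expect_true(sum(cs$noisy) >= 1)
  # a repeat query returns the same observed labels
  cs2 <- make_noisy_oracle(cov, rate = 0.1, seed = 3)(pairs)
  expect_identical(cs2$observed, cs$observed)
})

test_that("informative selection respects the queried set, budget, and fallback", {
  b <- small_bench(N = 300)
  pr <- occlean:::propagate_memories(b$network, slpa_params(rounds = 30,
                                                            seed = 4))
  cov <- run_slpa(b$network, slpa_params(rounds = 30, seed = 4))
  sel <- select_informative_pairs(b$network, cov, pr$mem,
                                  already_queried = character(0),
                                  budget = 50, seed = 5)
  expect_lte(nrow(sel), 50)
  expect_gte(nrow(sel), 1)
  keys <- occlean:::pair_keys(sel[, 1], sel[, 2])
  expect_false(any(duplicated(keys)))
  sel2 <- select_informative_pairs(b$network, cov, pr$mem,
                                   already_queried = keys, budget = 50,
                                   seed = 6)
  expect_length(intersect(occlean:::pair_keys(sel2[, 1], sel2[, 2]), keys), 0)

  # zero-entropy memories: pure uniform fallback still fills the budget
  mem0 <- matrix(rep(seq_len(igraph::vcount(b$network)), 11),
                 ncol = 11)
  sel3 <- select_informative_pairs(b$network, cov, mem0,
                                   budget = 20, seed = 7)
  expect_equal(nrow(sel3), 20)
})

test_that("selection targets the nodes with mixed label memories first", {
  b <- small_bench(N = 300)
  g <- b$network
  ids <- node_ids(g)
  n <- igraph::vcount(g)
  mem <- matrix(rep(seq_len(n), 11), ncol = 11)   # everyone certain...
  uncertain <- c(5L, 50L)
  mem[5L, ] <- rep(c(5L, 6L), length.out = 11)    # ...except two nodes
  mem[50L, ] <- rep(c(50L, 51L), length.out = 11)
  cov <- run_slpa(g, slpa_params(rounds = 30, seed = 4))
  sel <- select_informative_pairs(g, cov, mem, budget = 4, seed = 9)
  touched <- unique(c(sel[, 1], sel[, 2]))
  expect_true(all(apply(sel, 1, function(p)
    any(p %in% ids[uncertain]))))
})

test_that("the active loop respects budgets, accumulates, and is deterministic", {
  b <- small_bench(N = 300, seed = 23)
  cfg <- acslpa_config(iterations = 3, total_budget = 300,
                       cleaning = default_config("small", "traditional"),
                       slpa = slpa_params(rounds = 40, seed = 1),
                       seed = 11)
  cache <- feature_cache(b$network, seed = 1)
  res <- run_acslpa(b$network, b$cover, cfg, cache = cache)
  expect_lte(sum(res$provenance$queried), 300)
  expect_equal(nrow(res$provenance), 3)
  # conservation: kept + discarded = queried
  expect_equal(nrow(res$constraints) + nrow(res$discarded),
               sum(res$provenance$queried))
  res2 <- run_acslpa(b$network, b$cover, cfg, cache = cache)
  expect_identical(res$cover, res2$cover)
  expect_identical(res$constraints, res2$constraints)
})

test_that("a single clean iteration without cleaning equals PC-SLPA on the raw set", {
  b <- small_bench(N = 300, seed = 29)
  cfg <- acslpa_config(iterations = 1, total_budget = 100, noise_rate = 0,
                       clean = FALSE, slpa = slpa_params(rounds = 40,
                                                         seed = 2),
                       seed = 13)
  res <- run_acslpa(b$network, b$cover, cfg)
  direct <- run_pcslpa(b$network, res$constraints,
                       slpa_params(40, 0.1, occlean:::child_seed(13, 500L)))
  expect_identical(res$cover, direct)
})

test_that("pooled detector evidence does not degrade as constraints accumulate", {
  b <- small_bench(N = 300, seed = 31)
  cache <- feature_cache(b$network, seed = 3)
  auc_at <- function(iters, seed) {
    cs <- collect_active_constraints(b$network, b$cover, iterations = iters,
                                     total_budget = iters * 150,
                                     slpa = slpa_params(rounds = 40,
                                                        seed = 1),
                                     rate = 0.1, seed = seed)
    constraint_noise_auc(cs, b$network,
                         detector_spec("isolation_forest"), seed = 2,
                         cache = cache)["CL"]
  }
  small_pool <- mean(vapply(1:3, function(s) auc_at(1, s), 0), na.rm = TRUE)
  big_pool <- mean(vapply(1:3, function(s) auc_at(4, s), 0), na.rm = TRUE)
  expect_gte(big_pool, small_pool - 0.05)
})
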
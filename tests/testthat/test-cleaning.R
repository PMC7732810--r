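test_that("default configurations wire the documented model pairings", {
  hs <- default_config("small", "hybrid")
  expect_s3_class(hs$ml_model, "ae_architecture")
  expect_equal(hs$ml_model$dims, rep(7L, 3))      # AE1_L1
  expect_gt(hs$ml_model$l1, 0)
  expect_s3_class(hs$cl_model, "encoder_detector")
  expect_equal(hs$cl_model$encoder$dims, c(7L, 6L, 5L, 3L, 5L, 6L, 7L))
  expect_equal(hs$cl_model$detector$family, "isolation_forest")

  hl <- default_config("large", "autoencoder")
  expect_equal(hl$ml_model$dims, rep(7L, 5))      # AE2_L1
  expect_equal(hl$ml_model$epochs, 30L)
  expect_equal(hl$cl_model$dims, rep(7L, 7))      # AE3_L1

  tr <- default_config("small", "traditional")
  expect_equal(tr$ml_model$family, "ocsvm")
  expect_equal(tr$cl_model$family, "isolation_forest")

  de <- default_config("large", "deep_embedding")
  expect_equal(de$ml_model$encoder$dims, c(7L, 5L, 3L, 5L, 7L))  # AE2
  expect_equal(de$ml_model$detector$family, "ocsvm")
})

test_that("cleaning partitions the input and is deterministic", {
  b <- small_bench(N = 300)
  cache <- feature_cache(b$network, seed = 2)
  cs <- collect_active_constraints(b$network, b$cover, iterations = 2,
                                   total_budget = 400,
                                   slpa = slpa_params(rounds = 50, seed = 1),
                                   rate = 0.1, seed = 3)
  cfg <- default_config("small", "traditional")  # fast detectors
  res <- clean_constraint_set(cs, b$network, cfg, seed = 5, cache = cache)
  key <- function(x) paste(x$u, x$v)
  expect_setequal(c(key(res$kept), key(res$discarded)), key(cs))
  expect_length(intersect(key(res$kept), key(res$discarded)), 0)
  res2 <- clean_constraint_set(cs, b$network, cfg, seed = 5, cache = cache)
  expect_identical(res$kept, res2$kept)
  # provenance log has one row per executed round
  expect_true(all(res$log$fitted > 0))
  expect_lte(max(res$log$round), cfg$sub_iterations)
})

test_that("clean views lose at most about the contamination floor", {
  b <- small_bench(N = 300)
  cache <- feature_cache(b$network, seed = 2)
  cs <- collect_active_constraints(b$network, b$cover, iterations = 2,
                                   total_budget = 400,
                                   slpa = slpa_params(rounds = 50, seed = 1),
                                   rate = 0, seed = 3)
  cfg <- cleaning_config("traditional", detector_spec("isolation_forest"),
                         detector_spec("isolation_forest"),
                         sub_iterations = 1L)
  res <- clean_constraint_set(cs, b$network, cfg, seed = 7, cache = cache)
  frac <- nrow(res$discarded) / nrow(cs)
  expect_lte(frac, 0.2)  # never more than twice the 10% contamination
})

test_that("an undersized view passes through with a warning", {
  b <- small_bench(N = 300)
  cache <- feature_cache(b$network, seed = 2)
  ids <- node_ids(b$network)
  # constraints heavy on ML, almost no CL
  cs <- collect_active_constraints(b$network, b$cover, iterations = 1,
                                   total_budget = 60,
                                   slpa = slpa_params(rounds = 40, seed = 2),
                                   rate = 0, seed = 5)
  few_cl <- cs[cs$observed == "ML", ][1:30, ]
  cl_rows <- cs[cs$observed == "CL", ]
  mini <- occlean:::combine_constraints(few_cl, cl_rows[1:min(3, nrow(cl_rows)), ])
  cfg <- default_config("small", "traditional")
  expect_warning(res <- clean_constraint_set(mini, b$network, cfg, seed = 1,
                                             cache = cache),
                 "too small")
  expect_true(all(mini$observed[!paste(mini$u, mini$v) %in%
                                  paste(res$discarded$u, res$discarded$v)] %in%
                    c("ML", "CL")))
  # the tiny CL view survives untouched
  expect_true(all(paste(cl_rows[1:min(3, nrow(cl_rows)), "u"]) %in%
                    paste(res$kept$u)))
})

test_that("planted feature outliers in the ML view are mostly discarded", {
  b <- small_bench(N = 300, seed = 17)
  cache <- feature_cache(b$network, seed = 2)
  cov <- b$cover
  ids <- node_ids(b$network)
  g <- b$network
  # 90 true ML pairs (adjacent, same community) + 10 flipped CL pairs
  idx <- occlean:::membership_index(cov)
  el <- igraph::as_edgelist(g, names = TRUE)
  el <- matrix(as.integer(el), ncol = 2)
  same <- vapply(seq_len(nrow(el)), function(i)
    length(intersect(idx[[as.character(el[i, 1])]],
                     idx[[as.character(el[i, 2])]])) > 0, TRUE)
  ml_pool <- el[same, ][1:90, ]
  A <- igraph::as_adjacency_matrix(g)
  names_g <- igraph::V(g)$name
  withr::with_seed(9, {
    far <- t(replicate(200, sample(ids, 2)))
    lab <- vapply(seq_len(nrow(far)), function(i)
      length(intersect(idx[[as.character(far[i, 1])]],
                       idx[[as.character(far[i, 2])]])) > 0, TRUE)
    dist_ok <- A[cbind(match(as.character(far[, 1]), names_g),
                       match(as.character(far[, 2]), names_g))] == 0
  })
  cl_pool <- far[!lab & dist_ok, ][1:10, ]
  u <- c(ml_pool[, 1], cl_pool[, 1]); v <- c(ml_pool[, 2], cl_pool[, 2])
  keep <- !duplicated(paste(pmin(u, v), pmax(u, v)))
  cs <- constraint_set(u[keep], v[keep], "ML",
                       c(rep("ML", 90), rep("CL", 10))[keep])
  cfg <- default_config("small", "hybrid")
  res <- clean_constraint_set(cs, b$network, cfg, seed = 3, cache = cache)
  planted_gone <- sum(res$discarded$noisy)
  expect_gte(planted_gone, 8)
})

test_that("recheck recovers tightly clustered correct rows and is a subset", {
  b <- small_bench(N = 300)
  cache <- feature_cache(b$network, seed = 2)
  cs <- collect_active_constraints(b$network, b$cover, iterations = 2,
                                   total_budget = 400,
                                   slpa = slpa_params(rounds = 50, seed = 1),
                                   rate = 0, seed = 3)
  cfg <- default_config("small", "traditional")
  expect_equal(nrow(recheck_discarded(constraint_set(), b$network, cfg)), 0)
  res <- clean_constraint_set(cs, b$network, cfg, seed = 5, cache = cache)
  rec <- recheck_discarded(res$discarded, b$network, cfg, seed = 6,
                           cache = cache)
  key <- function(x) paste(x$u, x$v)
  expect_true(all(key(rec) %in% key(res$discarded)))
})
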
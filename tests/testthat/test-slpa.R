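test_that("SLPA recovers two bridged cliques and a single clique", {
  g <- two_clique_graph(5)
  hits <- 0
  for (s in 1:10) {
    cov <- run_slpa(g, slpa_params(rounds = 100, r = 0.1, seed = s))
    key <- vapply(cov, paste, "", collapse = ",")
    if (all(c("1,2,3,4,5", "6,7,8,9,10") %in% key) ||
        (length(cov) == 2 && setequal(unlist(cov), 1:10) &&
         all(vapply(cov, function(cm) all(cm <= 5) || all(cm >= 6), TRUE))))
      hits <- hits + 1
  }
  expect_gte(hits, 9)

  clique <- graph_from_edges(t(utils::combn(1:6, 2)))
  ok <- 0
  for (s in 1:5) {
    cov <- run_slpa(clique, slpa_params(rounds = 60, r = 0.1, seed = s))
    if (any(vapply(cov, length, 1L) == 6)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("threshold r = 0.5 forbids overlapping membership", {
  b <- small_bench(N = 300, On = 0.2)
  cov <- run_slpa(b$network, slpa_params(rounds = 50, r = 0.5, seed = 2))
  memb <- table(unlist(cov))
  expect_true(all(memb == 1))
})

test_that("every node lands in at least one community, deterministically per seed", {
  b <- small_bench(N = 300)
  cov1 <- run_slpa(b$network, slpa_params(seed = 5))
  cov2 <- run_slpa(b$network, slpa_params(seed = 5))
  expect_identical(cov1, cov2)
  expect_setequal(unlist(cov1), node_ids(b$network))
  expect_gte(length(cov1), 1)
})

test_that("must-link guidance merges cliques that SLPA keeps apart", {
  g <- two_clique_graph(5)
  cross <- expand.grid(u = 1:5, v = 6:10)
  cs <- constraint_set(cross$u, cross$v, rep("ML", nrow(cross)))
  cov <- run_pcslpa(g, cs, slpa_params(rounds = 100, r = 0.1, seed = 3))
  # every cross pair must share a community; the top community spans both sides
  idx <- occlean:::membership_index(cov)
  for (i in seq_len(nrow(cross)))
    expect_true(length(intersect(idx[[as.character(cross$u[i])]],
                                 idx[[as.character(cross$v[i])]])) > 0)
  expect_true(any(vapply(cov, function(cm)
    any(cm <= 5) && any(cm >= 6), TRUE)))
})

test_that("cannot-link constraints are never violated in the output", {
  clique <- graph_from_edges(t(utils::combn(1:8, 2)))
  cs <- constraint_set(c(1, 2), c(5, 6), c("CL", "CL"))
  for (s in 1:5) {
    cov <- run_pcslpa(clique, cs, slpa_params(rounds = 60, r = 0.1, seed = s))
    idx <- occlean:::membership_index(cov)
    expect_length(intersect(idx[["1"]], idx[["5"]]), 0)
    expect_length(intersect(idx[["2"]], idx[["6"]]), 0)
  }
})

test_that("an empty constraint set reduces PC-SLPA to SLPA", {
  b <- small_bench(N = 300)
  p <- slpa_params(rounds = 50, seed = 9)
  expect_identical(run_pcslpa(b$network, constraint_set(), p),
                   run_slpa(b$network, p))
})

test_that("constrained propagation satisfies CL and improves ML agreement on benchmarks", {
  b <- small_bench(N = 300, mu = 0.3, On = 0.1, Om = 2, seed = 13)
  cs <- collect_active_constraints(b$network, b$cover, iterations = 3,
                                   total_budget = 600,
                                   slpa = slpa_params(rounds = 50, seed = 1),
                                   rate = 0, seed = 4)
  p <- slpa_params(rounds = 50, seed = 21)
  cov_u <- run_slpa(b$network, p)
  cov_c <- run_pcslpa(b$network, cs, p)
  sat <- function(cov, view) {
    idx <- occlean:::membership_index(cov)
    rows <- cs[cs$observed == view, ]
    share <- vapply(seq_len(nrow(rows)), function(i)
      length(intersect(idx[[as.character(rows$u[i])]],
                       idx[[as.character(rows$v[i])]])) > 0, TRUE)
    mean(share)
  }
  expect_equal(sat(cov_c, "CL"), 0)  # share-rate of CL pairs must be zero
  expect_gt(sat(cov_c, "ML"), sat(cov_u, "ML"))
  expect_error(run_pcslpa(b$network,
                          constraint_set(1, 99999, "ML"), p), "absent")
})
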
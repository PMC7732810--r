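test_that("edge lists parse, collapse duplicates, and reject self-loops", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "0 1", "1 2", "2 0", "", "1 0"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)  # "1 0" collapses onto "0 1"

  writeLines(c("0 1", "0 0"), f)
  expect_error(read_edge_list(f), "self-loop at line 2")
  writeLines(c("0 1", "a b"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines(c("0 1 2"), f)
  expect_error(read_edge_list(f), "line 1")
})

test_that("edge list round trip reproduces the edge set", {
  b <- small_bench()
  f <- withr::local_tempfile()
  write_edge_list(b$network, f)
  g2 <- read_edge_list(f)
  key <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g2), key(b$network))
})

test_that("community files parse and round trip", {
  f <- withr::local_tempfile()
  writeLines(c("0 1 2", "2 3"), f)
  cov <- read_community_file(f)
  expect_length(cov, 2)
  expect_equal(cov[[1]], c(0L, 1L, 2L))
  expect_equal(cov[[2]], c(2L, 3L))

  writeLines(character(0), f)
  expect_length(read_community_file(f), 0)
  writeLines("5", f)
  expect_equal(read_community_file(f)[[1]], 5L)
  writeLines("1 x", f)
  expect_error(read_community_file(f), "non-integer")

  f2 <- withr::local_tempfile()
  write_community_file(random_cover(), f2)
  cov2 <- read_community_file(f2)
  expect_equal(lapply(cov2, identity), lapply(random_cover(), identity))
})

test_that("ground-truth filtering applies size, density, dedup and min-size rules", {
  # toy graph: three communities of sizes 3, 6, 10 plus an isolated-ish chain
  g <- graph_from_edges(t(utils::combn(1:19, 2)))  # complete graph, density 1 everywhere
  cov <- community_cover(list(1:3, 4:9, 10:19))
  out <- filter_ground_truth(cov, g, top_k = 10, min_size = 5,
                             density_quartile = FALSE)
  expect_equal(sort(lengths(out)), c(6L, 10L))

  # duplicates collapse
  cov2 <- community_cover(list(1:5, 1:5, 6:10))
  out2 <- filter_ground_truth(cov2, g, top_k = 10, min_size = 1,
                              density_quartile = FALSE)
  expect_length(out2, 2)

  # 8 communities with distinct densities: the 2 least dense go
  edges <- list()
  comms <- list()
  base <- 0L
  for (i in 1:8) {
    sz <- 6L
    ids <- base + seq_len(sz)
    pairs <- t(utils::combn(ids, 2))
    keep <- seq_len(nrow(pairs)) <= (i + 5)  # increasing internal density
    edges[[i]] <- pairs[keep, , drop = FALSE]
    comms[[i]] <- ids
    base <- base + sz
  }
  g3 <- graph_from_edges(do.call(rbind, edges))
  out3 <- filter_ground_truth(community_cover(comms), g3, top_k = 100,
                              min_size = 1)
  expect_length(out3, 6)
  expect_false(any(vapply(out3, function(cm) all(cm == comms[[1]]), TRUE)))
  expect_false(any(vapply(out3, function(cm) all(cm == comms[[2]]), TRUE)))

  # error on nodes absent from the network
  expect_error(filter_ground_truth(community_cover(list(c(1, 999))), g),
               "absent")
})

test_that("filtering output is a subset and the deterministic steps are idempotent", {
  b <- small_bench()
  out <- filter_ground_truth(b$cover, b$network, top_k = 20, min_size = 12)
  key <- function(cov) vapply(cov, paste, "", collapse = ",")
  expect_true(all(key(out) %in% key(b$cover)))
  again <- filter_ground_truth(out, b$network, top_k = 20, min_size = 12,
                               density_quartile = FALSE)
  expect_identical(key(again), key(out))
})
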
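# Small graphs and covers built in code, shared across test files.

# graph from an integer edge matrix
graph_from_edges <- function(edges) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(apply(edges, 1L, paste, collapse = " "), f)
  read_edge_list(f)
}

# a triangle on nodes 1..3
triangle_graph <- function() graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1)))

# two k-cliques (1..k and k+1..2k) joined by the single bridge edge (k, k+1)
two_clique_graph <- function(k = 5) {
  e1 <- t(utils::combn(seq_len(k), 2))
  e2 <- t(utils::combn(k + seq_len(k), 2))
  graph_from_edges(rbind(e1, e2, c(k, k + 1)))
}

# random overlapping cover over n nodes
random_cover <- function(n = 30, k = 4, seed = 1) {
  withr::with_seed(seed, {
    comms <- lapply(seq_len(k), function(i)
      sample.int(n, sample(3:max(4, n %/% 2), 1)))
    community_cover(comms)
  })
}

# deterministic small benchmark, memoised per session to keep tests fast
small_bench <- local({
  memo <- new.env(parent = emptyenv())
  function(N = 300, mu = 0.1, On = 0.1, Om = 2, seed = 7) {
    key <- paste(N, mu, On, Om, seed)
    if (!exists(key, envir = memo))
      assign(key, generate_benchmark(benchmark_params(
        N = N, mu = mu, On = On, Om = Om, C_min = 10, C_max = 50,
        seed = seed)), envir = memo)
    get(key, envir = memo)
  }
})
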
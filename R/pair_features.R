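# Compressed sparse adjacency (0-based, sorted neighbor lists) used by the
# compiled propagation and embedding routines.
graph_csr <- function(network) {
  n <- igraph::vcount(network)
  adjl <- igraph::as_adj_list(network, mode = "all")
  adjl <- lapply(adjl, function(x) sort(as.integer(x)) - 1L)
  list(adj = as.integer(unlist(adjl, use.names = FALSE)),
       ptr = c(0L, cumsum(vapply(adjl, length, 1L))),
       n = n)
}

# Sparse symmetric adjacency matrix (internal vertex indexing).
adjacency_sparse <- function(network) {
  igraph::as_adjacency_matrix(network, sparse = TRUE) * 1
}

#' All-pairs SimRank similarity by fixed-point iteration
#'
#' Iterates the SimRank recurrence
#' `s(u, v) = C / (|N(u)||N(v)|) * sum over neighbor pairs of s(a, b)` with
#' `s(u, u) = 1`, and `s(u, v) = 0` whenever either node has no neighbors.
#' Stops when the maximum absolute change drops below `tol` or after
#' `max_iter` sweeps.
#'
#' @param network igraph graph.
#' @param C Decay factor in (0, 1).
#' @param tol Convergence tolerance on the max absolute change.
#' @param max_iter Maximum number of sweeps.
#' @return Dense symmetric similarity matrix with node ids as dimnames.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3"), f)
#' g <- read_edge_list(f)
#' compute_simrank(g)["1", "3"] # 0.8: the two path ends share neighbor 2
compute_simrank <- function(network, C = 0.8, tol = 1e-4, max_iter = 100L) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("network is empty")
  A <- adjacency_sparse(network)
  deg <- Matrix::colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  W <- A %*% Matrix::Diagonal(x = inv)  # column-normalized adjacency
  S <- diag(1, n)
  for (it in seq_len(max_iter)) {
    S_new <- C * as.matrix(Matrix::t(W) %*% (S %*% W))
    diag(S_new) <- 1
    delta <- max(abs(S_new - S))
    S <- S_new
    if (delta < tol) break
  }
  isolated <- which(deg == 0)
  if (length(isolated)) {  # no neighbors: similarity 0 to everything else
    S[isolated, ] <- 0
    S[, isolated] <- 0
    diag(S) <- 1
  }
  dimnames(S) <- list(igraph::V(network)$name, igraph::V(network)$name)
  S
}

#' Random-walk skip-gram node embedding
#'
#' Generates biased random walks (return bias `p`, in-out bias `q`; both 1 by
#' default, giving uniform walks) and trains a skip-gram model with negative
#' sampling on the walk corpus. Deterministic given `seed`.
#'
#' @param network igraph graph.
#' @param dims Embedding dimensionality.
#' @param walks_per_node,walk_length Corpus size parameters.
#' @param window Skip-gram context window.
#' @param p,q Return and in-out biases of the second-order walk.
#' @param negative Negative samples per context pair.
#' @param lr Initial learning rate (linearly decayed).
#' @param seed Integer seed.
#' @return Numeric matrix, one row per node (rownames = node ids).
#' @export
compute_embedding <- function(network, dims = 64L, walks_per_node = 10L,
                              walk_length = 80L, window = 10L, p = 1,
                              q = 1, negative = 5L, lr = 0.025, seed = 1L) {
  csr <- graph_csr(network)
  emb <- node2vec_core(csr$adj, csr$ptr, as.integer(dims),
                       as.integer(walks_per_node), as.integer(walk_length),
                       as.integer(window), p, q, as.integer(negative), lr,
                       as.integer(seed))
  rownames(emb) <- igraph::V(network)$name
  emb
}

#' Precompute the expensive per-network feature inputs
#'
#' Computes and caches the SimRank table, the node embedding, the sparse
#' adjacency and the per-pair feature vectors so that repeated constraint-set
#' feature extraction on the same network (as in the active loop) is cheap.
#' SimRank is run for `simrank_iter` sweeps, the iteration count reported as
#' sufficient in the original fixed-point formulation.
#'
#' @param network igraph graph.
#' @param simrank_iter SimRank sweeps used for the cached table.
#' @param embedding_args List of overrides passed to [compute_embedding()].
#' @param seed Seed for the embedding.
#' @return A `feature_cache` environment.
#' @export
feature_cache <- function(network, simrank_iter = 5L, embedding_args = list(),
                          seed = 1L) {
  cache <- new.env(parent = emptyenv())
  cache$network <- network
  cache$A <- adjacency_sparse(network)
  cache$deg <- Matrix::colSums(cache$A)
  cache$sim <- compute_simrank(network, max_iter = simrank_iter)
  emb <- do.call(compute_embedding,
                 c(list(network = network, seed = seed), embedding_args))
  cache$emb <- emb / pmax(sqrt(rowSums(emb^2)), 1e-12)  # unit rows
  cache$pairs <- new.env(parent = emptyenv())  # key "u_v" -> raw 7-vector
  class(cache) <- "feature_cache"
  cache
}

feature_names <- c("shared_edge", "common_neighbors", "neighborhood_jaccard",
                   "shortest_path_score", "cosine_similarity", "simrank",
                   "embedding_similarity")

# raw per-pair features for internal vertex indices iu, iv (same length)
pair_feature_block <- function(cache, iu, iv) {
  A <- cache$A; deg <- cache$deg
  m <- length(iu)
  Au <- A[iu, , drop = FALSE]
  Av <- A[iv, , drop = FALSE]
  cn <- Matrix::rowSums(Au * Av)
  shared <- as.numeric(A[cbind(iu, iv)] > 0)
  uni <- deg[iu] + deg[iv] - cn
  jac <- ifelse(uni > 0, cn / uni, 0)
  cosim <- ifelse(deg[iu] * deg[iv] > 0, cn / sqrt(deg[iu] * deg[iv]), 0)
  # shortest paths: BFS from each unique source, chunked
  g <- cache$network
  sp <- numeric(m)
  us <- unique(iu)
  for (chunk in split(us, ceiling(seq_along(us) / 500))) {
    d <- igraph::distances(g, v = chunk, to = igraph::V(g))
    rows <- match(iu, chunk)
    inchunk <- which(!is.na(rows))
    sp[inchunk] <- d[cbind(rows[inchunk], iv[inchunk])]
  }
  spscore <- ifelse(is.finite(sp) & sp > 0, 1 / sp, 0)
  sim <- cache$sim[cbind(iu, iv)]
  embsim <- rowSums(cache$emb[iu, , drop = FALSE] *
                    cache$emb[iv, , drop = FALSE])
  cbind(shared_edge = shared, common_neighbors = cn,
        neighborhood_jaccard = jac, shortest_path_score = spscore,
        cosine_similarity = cosim, simrank = sim,
        embedding_similarity = embsim)
}

#' Extract the 7-dimensional topological feature matrix for a constraint set
#'
#' Per pair (u, v): `shared_edge` (edge indicator), `common_neighbors`,
#' `neighborhood_jaccard`, `shortest_path_score` (reciprocal geodesic
#' distance, 0 when disconnected), `cosine_similarity` of adjacency rows,
#' `simrank`, and cosine `embedding_similarity`. Each column is then min-max
#' scaled to \[0, 1\] over the constraint set (a constant column maps to 0).
#'
#' @param cs A [constraint_set()].
#' @param network igraph graph containing all constraint nodes.
#' @param cache Optional [feature_cache()] for the network; built on the fly
#'   (with default settings) when absent.
#' @return A `feature_matrix` list with elements `raw`, `scaled` (matrices,
#'   rows aligned to `cs`), and `ranges` (the per-column min/max used).
#' @export
extract_features <- function(cs, network, cache = NULL) {
  if (is.null(cache)) cache <- feature_cache(network)
  names_g <- igraph::V(cache$network)$name
  iu <- match(as.character(cs$u), names_g)
  iv <- match(as.character(cs$v), names_g)
  if (anyNA(iu) || anyNA(iv))
    stop("constraint node absent from network")
  key <- paste0(cs$u, "_", cs$v)
  raw <- matrix(NA_real_, nrow(cs), length(feature_names),
                dimnames = list(NULL, feature_names))
  known <- vapply(key, exists, TRUE, envir = cache$pairs)
  if (any(known))
    raw[known, ] <- t(vapply(key[known], get, numeric(7), envir = cache$pairs))
  if (any(!known)) {
    blk <- pair_feature_block(cache, iu[!known], iv[!known])
    raw[!known, ] <- blk
    for (i in which(!known)) assign(key[i], raw[i, ], envir = cache$pairs)
  }
  lo <- apply(raw, 2L, min); hi <- apply(raw, 2L, max)
  span <- hi - lo
  scaled <- sweep(raw, 2L, lo)
  scaled <- sweep(scaled, 2L, ifelse(span > 0, span, 1), "/")
  scaled[, span == 0] <- 0
  structure(list(raw = raw, scaled = scaled,
                 ranges = rbind(min = lo, max = hi)),
            class = "feature_matrix")
}

#' Write a feature matrix as TSV
#'
#' @param fm A `feature_matrix` from [extract_features()].
#' @param path Output path.
#' @param which `"scaled"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path, which = c("scaled", "raw")) {
  which <- match.arg(which)
  utils::write.table(fm[[which]], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
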
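#' Read an undirected simple graph from a whitespace-separated edge list
#'
#' Each non-comment line must hold two integer node ids. Duplicate lines and
#' reversed duplicates collapse to a single undirected edge; self-loops are
#' rejected. Lines starting with `#` and blank lines are ignored. Node ids may
#' be arbitrary integers; they are preserved as igraph vertex names.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::igraph] graph whose vertex names are
#'   the original integer ids (as character).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("0 1", "1 2", "2 0"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g) # 3
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad))
    stop("malformed edge at line ", keep[bad[1L]], ": expected two tokens")
  u <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2L)))
  nonint <- which(is.na(u) | is.na(v))
  if (length(nonint))
    stop("malformed edge at line ", keep[nonint[1L]], ": non-integer node id")
  loop <- which(u == v)
  if (length(loop))
    stop("self-loop at line ", keep[loop[1L]], ": node ", u[loop[1L]])
  build_network(cbind(u, v))
}

# Construct the canonical network object from an integer edge matrix.
build_network <- function(edges, nodes = NULL) {
  if (nrow(edges)) {
    lo <- pmin(edges[, 1L], edges[, 2L])
    hi <- pmax(edges[, 1L], edges[, 2L])
    dup <- duplicated(cbind(lo, hi))
    lo <- lo[!dup]; hi <- hi[!dup]
  } else lo <- hi <- integer(0)
  nodes <- sort(unique(c(nodes, lo, hi)))
  igraph::graph_from_data_frame(
    data.frame(from = as.character(lo), to = as.character(hi)),
    directed = FALSE, vertices = data.frame(name = as.character(nodes)))
}

#' Write a graph as a whitespace-separated edge list
#'
#' @param network An undirected igraph graph (integer vertex names).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L]), path)
  invisible(path)
}

#' Integer node ids of a network
#'
#' @param network An igraph graph with integer vertex names.
#' @return Integer vector of node ids.
#' @export
node_ids <- function(network) as.integer(igraph::V(network)$name)

#' Construct an overlapping community cover
#'
#' A cover is an ordered list of non-empty integer node-id sets; a node may
#' appear in several communities.
#'
#' @param communities List of integer vectors (node ids).
#' @return A `community_cover` object.
#' @export
community_cover <- function(communities) {
  communities <- lapply(communities, function(x) sort(unique(as.integer(x))))
  if (any(vapply(communities, length, 1L) == 0L))
    stop("every community must be non-empty")
  structure(communities, class = "community_cover")
}

#' @export
print.community_cover <- function(x, ...) {
  sz <- vapply(x, length, 1L)
  cat("community cover:", length(x), "communities,",
      length(unique(unlist(x))), "nodes; sizes",
      if (length(sz)) paste0("[", min(sz), ", ", max(sz), "]") else "[]", "\n")
  invisible(x)
}

#' Read an overlapping cover in SNAP community-file dialect
#'
#' One community per line, whitespace-separated node ids; empty lines skipped;
#' line order preserved.
#'
#' @param path Path to the community file.
#' @return A [community_cover()] object.
#' @export
read_community_file <- function(path) {
  if (!file.exists(path)) stop("community file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(community_cover(list()))
  comms <- lapply(seq_along(lines), function(i) {
    ids <- suppressWarnings(as.integer(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (anyNA(ids)) stop("non-integer node id in community on line ", i)
    ids
  })
  community_cover(comms)
}

#' Write a cover in SNAP community-file dialect
#'
#' @param cover A [community_cover()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_community_file <- function(cover, path) {
  writeLines(vapply(cover, paste, "", collapse = "\t"), path)
  invisible(path)
}

# Internal edge density of each community: 2 m_C / (n_C (n_C - 1)); singletons
# get density 0.
community_densities <- function(cover, network) {
  vapply(cover, function(cm) {
    n <- length(cm)
    if (n < 2L) return(0)
    sub <- igraph::induced_subgraph(network, as.character(cm))
    2 * igraph::ecount(sub) / (n * (n - 1))
  }, 0)
}

#' Filter a ground-truth cover by size, internal density, and duplication
#'
#' Applies, in order: keep the `top_k` largest communities; rank survivors by
#' internal edge density and discard the bottom quartile (`floor(0.25 * count)`
#' lowest-density communities, ties broken by discarding the smaller community
#' first); remove exact duplicate node sets; remove communities smaller than
#' `min_size`.
#'
#' @param cover A [community_cover()].
#' @param network The igraph graph the communities live on.
#' @param top_k Number of largest communities to retain initially.
#' @param min_size Minimum community size kept at the final step.
#' @param density_quartile Apply the bottom-quartile density cut? (default TRUE)
#' @return The filtered [community_cover()].
#' @export
filter_ground_truth <- function(cover, network, top_k = 5000L, min_size = 5L,
                                density_quartile = TRUE) {
  if (!length(cover)) stop("cover is empty")
  stopifnot(top_k >= 1L, min_size >= 1L)
  ids <- node_ids(network)
  missing <- setdiff(unique(unlist(cover)), ids)
  if (length(missing))
    stop("community node(s) absent from network: ",
         paste(head(missing, 5L), collapse = ", "))
  sz <- vapply(cover, length, 1L)
  keep <- order(sz, decreasing = TRUE)[seq_len(min(top_k, length(cover)))]
  keep <- sort(keep)  # preserve original order among survivors
  cover <- cover[keep]
  if (density_quartile && length(cover) >= 4L) {
    dens <- community_densities(cover, network)
    sz <- vapply(cover, length, 1L)
    drop_n <- floor(0.25 * length(cover))
    if (drop_n > 0L) {
      drop <- order(dens, sz)[seq_len(drop_n)]
      cover <- cover[-drop]
    }
  }
  key <- vapply(cover, paste, "", collapse = ",")
  cover <- cover[!duplicated(key)]
  cover <- cover[vapply(cover, length, 1L) >= min_size]
  community_cover(cover)
}
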
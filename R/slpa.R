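#' Parameters for speaker-listener label propagation
#'
#' @param rounds Number of propagation rounds T (each node's memory ends with
#'   `rounds + 1` entries including its self-initialization).
#' @param r Post-processing threshold in (0, 0.5\]: labels whose memory
#'   frequency falls below `r` are dropped.
#' @param seed Integer seed.
#' @return An `slpa_params` list.
#' @export
slpa_params <- function(rounds = 100L, r = 0.1, seed = 1L) {
  stopifnot(rounds >= 1L, r > 0, r <= 0.5)
  structure(list(rounds = as.integer(rounds), r = r, seed = as.integer(seed)),
            class = "slpa_params")
}

# internal: run the compiled propagation; constraints (if any) as a
# constraint_set on observed labels. Returns the memory matrix (1-based
# internal labels) plus the id mapping.
propagate_memories <- function(network, params, cs = NULL) {
  csr <- graph_csr(network)
  names_g <- igraph::V(network)$name
  to_idx0 <- function(ids) match(as.character(ids), names_g) - 1L
  ml <- cl <- matrix(integer(0), 0L, 2L)
  if (!is.null(cs) && nrow(cs)) {
    iu <- to_idx0(cs$u); iv <- to_idx0(cs$v)
    if (anyNA(iu) || anyNA(iv))
      stop("constraint references a node absent from the network")
    ml <- cbind(iu, iv)[cs$observed == "ML", , drop = FALSE]
    cl <- cbind(iu, iv)[cs$observed == "CL", , drop = FALSE]
  }
  mem <- slpa_core(csr$adj, csr$ptr, params$rounds, params$seed,
                   ml, cl, 2.0)
  list(mem = mem + 1L, names = names_g)
}

# memory matrix -> list of per-node surviving label sets (threshold r),
# label-less nodes keep their top label
memory_labels <- function(mem, r) {
  total <- ncol(mem)
  lapply(seq_len(nrow(mem)), function(i) {
    tab <- tabulate(mem[i, ], nbins = nrow(mem))
    keep <- which(tab / total >= r)
    if (!length(keep)) keep <- which.max(tab)
    keep
  })
}

# top label of a node and its count
top_label <- function(row) {
  tab <- table(row)
  lbl <- as.integer(names(tab)[which.max(tab)])
  c(label = lbl, count = max(tab))
}

# Build a cover from per-node label sets; duplicate communities merged.
labels_to_cover <- function(node_labels, names_g) {
  ln <- lengths(node_labels)
  nodes <- rep.int(as.integer(names_g), ln)
  labs <- unlist(node_labels, use.names = FALSE)
  comms <- unname(split(nodes, labs))
  comms <- lapply(comms, sort)
  key <- vapply(comms, paste, "", collapse = ",")
  community_cover(comms[!duplicated(key)])
}

#' Unsupervised speaker-listener label propagation (SLPA)
#'
#' Each node's memory starts with its own id; for `rounds` rounds every
#' listener (random order per round) collects one label from each neighbor
#' (sampled from the speaker's memory proportionally to frequency) and stores
#' the most frequent received label, ties broken at random. Post-processing
#' drops labels seen in less than a fraction `r` of the memory and assigns
#' each node to the communities of its surviving labels.
#'
#' @param network igraph graph.
#' @param params [slpa_params()].
#' @return A [community_cover()].
#' @export
run_slpa <- function(network, params = slpa_params()) {
  pr <- propagate_memories(network, params)
  labels_to_cover(memory_labels(pr$mem, params$r), pr$names)
}

#' Pairwise-constrained SLPA (PC-SLPA)
#'
#' As [run_slpa()], with constraint guidance: (a) must-link partners of the
#' listener also speak, and their labels carry doubled weight; (b) after each
#' round, any cannot-link pair agreeing on its top label has the weaker
#' attachment swap one copy for its runner-up label; (c) in post-processing,
#' unsatisfied must-link pairs have the stronger node's top label added to
#' the weaker node's label set, and cannot-link pairs sharing a community
#' have the weaker member removed (re-seeded as a singleton if left empty).
#' Cannot-link constraints are therefore always satisfied in the output;
#' must-link is encouraged without assuming transitivity.
#'
#' @param network igraph graph.
#' @param constraints A [constraint_set()]; observed labels are used.
#' @param params [slpa_params()].
#' @return A [community_cover()].
#' @export
run_pcslpa <- function(network, constraints, params = slpa_params()) {
  pr <- propagate_memories(network, params, constraints)
  finalize_pcslpa(pr, constraints, params$r)
}

finalize_pcslpa <- function(pr, constraints, r) {
  mem <- pr$mem
  node_labels <- memory_labels(mem, r)
  n <- nrow(mem)
  freq_of <- function(i, lbl) sum(mem[i, ] == lbl)
  to_idx <- function(ids) match(as.character(ids), pr$names)
  if (!is.null(constraints) && nrow(constraints)) {
    iu <- to_idx(constraints$u); iv <- to_idx(constraints$v)
    is_ml <- constraints$observed == "ML"
    # (c) must-link: bring unsatisfied pairs together
    for (j in which(is_ml)) {
      a <- iu[j]; b <- iv[j]
      if (length(intersect(node_labels[[a]], node_labels[[b]]))) next
      ta <- top_label(mem[a, ]); tb <- top_label(mem[b, ])
      if (ta["count"] >= tb["count"])
        node_labels[[b]] <- union(node_labels[[b]], ta["label"])
      else
        node_labels[[a]] <- union(node_labels[[a]], tb["label"])
    }
    # (c) cannot-link: hard separation; fresh singleton labels cannot clash
    fresh <- n
    for (j in which(!is_ml)) {
      a <- iu[j]; b <- iv[j]
      shared <- intersect(node_labels[[a]], node_labels[[b]])
      for (lbl in shared) {
        weak <- if (freq_of(a, lbl) < freq_of(b, lbl)) a else b
        node_labels[[weak]] <- setdiff(node_labels[[weak]], lbl)
        if (!length(node_labels[[weak]])) {
          fresh <- fresh + 1L
          node_labels[[weak]] <- fresh
        }
      }
    }
  }
  labels_to_cover(node_labels, pr$names)
}
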
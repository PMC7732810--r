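#' Emulate a (possibly noisy) pairwise-constraint oracle
#'
#' Answers any batch of unordered node pairs with must-link / cannot-link
#' labels derived from the ground-truth cover, then flips the labels of
#' `rate` times the smaller view of the batch (the label-flip noise
#' protocol). Labels are fixed once per pair for the oracle's lifetime.
#'
#' @param cover Ground-truth [community_cover()].
#' @param rate Noise level as a fraction of the smaller constraint view.
#' @param seed Integer seed.
#' @return A function `oracle(pairs)` returning a [constraint_set()].
#' @export
make_noisy_oracle <- function(cover, rate = 0.1, seed = 1L) {
  answered <- new.env(parent = emptyenv())  # key "u_v" -> observed label
  calls <- 0L
  function(pairs) {
    if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
    calls <<- calls + 1L
    cs <- annotate_pairs(pairs, cover)
    if (rate > 0 && nrow(cs))
      cs <- suppressWarnings(inject_noise(cs, rate, child_seed(seed, calls)))
    key <- paste0(cs$u, "_", cs$v)
    for (i in seq_len(nrow(cs))) {
      if (exists(key[i], envir = answered))
        cs$observed[i] <- get(key[i], envir = answered)
      else assign(key[i], cs$observed[i], envir = answered)
    }
    cs$noisy <- cs$observed != cs$true
    cs
  }
}

pair_keys <- function(u, v) paste0(pmin(u, v), "_", pmax(u, v))

# row-bind constraint sets preserving the class
combine_constraints <- function(a, b) {
  if (is.null(a) || !nrow(a)) return(b)
  if (is.null(b) || !nrow(b)) return(a)
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("constraint_set", "data.frame")
  out
}

#' Select informative node pairs for annotation
#'
#' Ranks nodes by the entropy of their propagation label memories
#' (membership uncertainty), then pairs each top-uncertain node with (i) its
#' highest-attachment neighbor (the neighbor whose memory most often holds
#' the node's own top label) and (ii) a sampled non-neighbor from a
#' different current community. When all memories are pure (zero entropy)
#' the selection falls back to uniform sampling of unqueried pairs, which is
#' also used to fill any remaining budget.
#'
#' @param network igraph graph.
#' @param cover Current working [community_cover()].
#' @param memories Memory matrix from the last propagation run (internal).
#' @param already_queried Character vector of `"u_v"` keys (u < v, node ids).
#' @param budget Maximum number of pairs to return.
#' @param seed Integer seed.
#' @return Two-column integer matrix of node pairs (possibly fewer than
#'   `budget` when the unqueried pool is exhausted).
#' @export
select_informative_pairs <- function(network, cover, memories,
                                     already_queried = character(0),
                                     budget = 100L, seed = 1L) {
  stopifnot(budget >= 1L)
  names_g <- igraph::V(network)$name
  ids <- as.integer(names_g)
  n <- length(ids)
  with_seed(seed, {
    taken <- new.env(parent = emptyenv())
    for (k in already_queried) assign(k, TRUE, envir = taken)
    sel_u <- integer(0); sel_v <- integer(0)
    add_pair <- function(ia, ib) {  # internal indices
      if (is.na(ia) || is.na(ib) || ia == ib) return(FALSE)
      k <- pair_keys(ids[ia], ids[ib])
      if (exists(k, envir = taken)) return(FALSE)
      assign(k, TRUE, envir = taken)
      sel_u <<- c(sel_u, ids[ia]); sel_v <<- c(sel_v, ids[ib])
      TRUE
    }
    H <- apply(memories, 1L, function(row) {
      p <- tabulate(match(row, unique(row)))
      p <- p / sum(p)
      -sum(p * log(p))
    })
    idx_of <- function(id) match(as.character(id), names_g)
    comm_has <- lapply(cover, function(cm) idx_of(cm))
    node_comm <- membership_index(stats::setNames(cover, NULL))
    adjl <- igraph::as_adj_list(network, mode = "all")
    if (max(H) > 0) {
      ord <- order(-H, seq_len(n))
      for (v in ord) {
        if (length(sel_u) >= budget) break
        if (H[v] == 0) break
        nb <- as.integer(adjl[[v]])
        tv <- top_label(memories[v, ])
        if (length(nb)) {
          att <- vapply(nb, function(w) sum(memories[w, ] == tv["label"]), 0)
          add_pair(v, nb[which.max(att)])
        }
        if (length(sel_u) >= budget) break
        vcomms <- node_comm[[as.character(ids[v])]] %||% integer(0)
        others <- setdiff(seq_along(cover), vcomms)
        if (length(others)) {
          cm <- comm_has[[others[sample.int(length(others), 1L)]]]
          cand <- setdiff(cm, c(v, nb))
          if (length(cand))
            add_pair(v, cand[sample.int(length(cand), 1L)])
        }
      }
    }
    # uniform fill of any remaining budget
    tries <- 0L
    max_tries <- 200L * budget
    while (length(sel_u) < budget && tries < max_tries) {
      tries <- tries + 1L
      ab <- sample.int(n, 2L)
      add_pair(ab[1L], ab[2L])
    }
    cbind(u = sel_u, v = sel_v)
  })
}

#' Configuration of the active constrained pipeline
#'
#' @param iterations Active-learning iterations.
#' @param total_budget Total pair-annotation budget; defaults to 2% of all
#'   node pairs capped at 5000.
#' @param cleaning A [cleaning_config()]; defaults to the hybrid process at
#'   the network's scale.
#' @param slpa [slpa_params()] for every propagation run.
#' @param noise_rate Oracle label-flip level (fraction of the smaller view).
#' @param clean Run the cleaning phase? (FALSE gives the uncleaned
#'   baseline.)
#' @param seed Master seed for the run.
#' @return An `acslpa_config`.
#' @export
acslpa_config <- function(iterations = 10L, total_budget = NULL,
                          cleaning = NULL, slpa = slpa_params(),
                          noise_rate = 0.1, clean = TRUE, seed = 1L) {
  stopifnot(iterations >= 1L)
  structure(list(iterations = as.integer(iterations),
                 total_budget = total_budget, cleaning = cleaning,
                 slpa = slpa, noise_rate = noise_rate, clean = clean,
                 seed = as.integer(seed)),
            class = "acslpa_config")
}

#' Active semi-supervised community detection with noise cleaning (AC-SLPA)
#'
#' Stage 1, per iteration: select informative pairs, have the (noisy) oracle
#' label them, pool the new constraints with the accumulated cleaned set,
#' clean the pool (models retrained each iteration), and run constrained
#' propagation with the kept constraints. Stage 2, after the loop: recheck
#' the accumulated discarded pool and merge recoveries back. Stage 3: a
#' final constrained propagation on the full accumulated cleaned set.
#'
#' @param network igraph graph.
#' @param cover Ground-truth [community_cover()] used to emulate the oracle
#'   (ignored when `oracle` is supplied).
#' @param config An [acslpa_config()].
#' @param oracle Optional oracle function (see [make_noisy_oracle()]).
#' @param reference Optional reference cover; when given, per-iteration
#'   overlapping NMI is recorded in the provenance.
#' @param cache Optional [feature_cache()] for the network.
#' @return List with `cover` (final communities), `constraints` (final
#'   cleaned set), `discarded`, and `provenance` (per-iteration counts).
#' @export
run_acslpa <- function(network, cover = NULL, config = acslpa_config(),
                       oracle = NULL, reference = NULL, cache = NULL) {
  n <- igraph::vcount(network)
  total_budget <- config$total_budget %||%
    min(5000L, max(config$iterations, round(0.02 * n * (n - 1) / 2)))
  per_iter <- ceiling(total_budget / config$iterations)
  cleaning <- config$cleaning %||%
    default_config(network_scale(network), "hybrid")
  oracle <- oracle %||% {
    if (is.null(cover)) stop("either `cover` or `oracle` must be supplied")
    make_noisy_oracle(cover, config$noise_rate, child_seed(config$seed, 1L))
  }
  if (config$clean && is.null(cache))
    cache <- feature_cache(network, seed = child_seed(config$seed, 2L))
  sl <- config$slpa
  pr <- propagate_memories(network,
                           slpa_params(sl$rounds, sl$r,
                                       child_seed(config$seed, 3L)))
  pc_plus <- constraint_set()
  discarded <- constraint_set()
  queried <- character(0)
  prov <- list()
  for (t in seq_len(config$iterations)) {
    budget_t <- min(per_iter, total_budget - length(queried))
    if (budget_t < 1L) break
    cover_cur <- labels_to_cover(memory_labels(pr$mem, sl$r), pr$names)
    pairs <- select_informative_pairs(network, cover_cur, pr$mem, queried,
                                      budget_t, child_seed(config$seed,
                                                           100L + t))
    if (!nrow(pairs)) break
    queried <- c(queried, pair_keys(pairs[, 1L], pairs[, 2L]))
    new_cs <- oracle(pairs)
    pool <- combine_constraints(pc_plus, new_cs)
    if (config$clean) {
      res <- clean_constraint_set(pool, network, cleaning,
                                  child_seed(config$seed, 200L + t), cache)
      pc_plus <- res$kept
      discarded <- combine_constraints(discarded, res$discarded)
    } else pc_plus <- pool
    sl_t <- slpa_params(sl$rounds, sl$r, child_seed(config$seed, 300L + t))
    if (nrow(pc_plus)) {
      pr <- propagate_memories(network, sl_t, pc_plus)
    } else {
      warning("no constraints kept after cleaning; falling back to ",
              "unsupervised propagation")
      pr <- propagate_memories(network, sl_t)
    }
    prov[[t]] <- data.frame(
      iteration = t, queried = nrow(pairs), kept = nrow(pc_plus),
      discarded = nrow(discarded),
      nmi = if (is.null(reference)) NA_real_ else
        overlapping_nmi(finalize_pcslpa(pr, pc_plus, sl$r), reference))
  }
  recovered <- constraint_set()
  if (config$clean && nrow(discarded)) {
    recovered <- recheck_discarded(discarded, network, cleaning,
                                   child_seed(config$seed, 400L), cache)
    if (nrow(recovered)) {
      pc_plus <- combine_constraints(pc_plus, recovered)
      keys_rec <- pair_keys(recovered$u, recovered$v)
      keep <- !(pair_keys(discarded$u, discarded$v) %in% keys_rec)
      discarded <- discarded[keep, , drop = FALSE]
    }
  }
  sl_f <- slpa_params(sl$rounds, sl$r, child_seed(config$seed, 500L))
  final_cover <- if (nrow(pc_plus)) {
    run_pcslpa(network, pc_plus, sl_f)
  } else {
    warning("no constraints accumulated; returning unsupervised result")
    run_slpa(network, sl_f)
  }
  list(cover = final_cover, constraints = pc_plus, discarded = discarded,
       provenance = do.call(rbind, prov),
       recovered = nrow(recovered))
}

#' Pool actively selected constraints without cleaning
#'
#' The detached harness for evaluating outlier detectors: runs the active
#' selection loop with a perfect oracle and no cleaning, pooling all
#' annotated pairs; label-flip noise at `rate` of the smaller view is then
#' injected once into the pooled set.
#'
#' @param network igraph graph.
#' @param cover Ground-truth cover for the oracle.
#' @param iterations,total_budget,slpa,seed As in [acslpa_config()].
#' @param rate Noise level injected into the pooled set.
#' @return A [constraint_set()] with hidden noise flags.
#' @export
collect_active_constraints <- function(network, cover, iterations = 10L,
                                       total_budget = NULL,
                                       slpa = slpa_params(), rate = 0.1,
                                       seed = 1L) {
  res <- run_acslpa(network, cover,
                    acslpa_config(iterations = iterations,
                                  total_budget = total_budget, slpa = slpa,
                                  noise_rate = 0, clean = FALSE,
                                  seed = seed))
  suppressWarnings(inject_noise(res$constraints, rate,
                                child_seed(seed, 999L)))
}
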
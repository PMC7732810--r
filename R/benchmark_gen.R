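#' Parameters for the overlapping benchmark generator
#'
#' Defaults mirror the standard benchmark ranges used throughout the package:
#' average degree 10, maximum degree 50, degree exponent 2, community-size
#' exponent 1, with the "small" regime pairing N = 1000 with community sizes
#' 10-50 and the "large" regime pairing N = 5000 with sizes 20-100.
#'
#' @param N Number of nodes.
#' @param k_avg Target average degree.
#' @param k_max Maximum degree.
#' @param t1 Degree power-law exponent.
#' @param t2 Community-size power-law exponent.
#' @param C_min,C_max Community size bounds.
#' @param mu Mixing parameter in \[0, 1\]: fraction of each node's edges that
#'   leave its communities.
#' @param On Fraction of nodes belonging to more than one community.
#' @param Om Number of memberships per overlapping node (>= 1).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `benchmark_params` list.
#' @export
benchmark_params <- function(N = 1000L, k_avg = 10, k_max = 50L, t1 = 2,
                             t2 = 1, C_min = 10L, C_max = 50L, mu = 0.1,
                             On = 0.1, Om = 2L, seed = 1L) {
  p <- list(N = as.integer(N), k_avg = k_avg, k_max = as.integer(k_max),
            t1 = t1, t2 = t2, C_min = as.integer(C_min),
            C_max = as.integer(C_max), mu = mu, On = On, Om = as.integer(Om),
            seed = as.integer(seed))
  stopifnot(p$C_min <= p$C_max, p$C_max <= p$N, p$mu >= 0, p$mu <= 1,
            p$On >= 0, p$On <= 1, p$Om >= 1, p$k_avg <= p$k_max)
  structure(p, class = "benchmark_params")
}

# sample() that never falls into the 1:x scalar trap
sample_vec <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

# Sample N degrees from a discrete truncated power law k^-t1 on [kmin, kmax]
# whose mean matches k_avg; the lower cut is a mixture of the two integer
# cuts bracketing the target mean.
sample_power_degrees <- function(N, t1, k_avg, k_max) {
  mean_for <- function(kmin) {
    k <- kmin:k_max
    w <- k^(-t1)
    sum(k * w) / sum(w)
  }
  means <- vapply(1:k_max, mean_for, 0)  # increasing in kmin
  if (k_avg <= means[1L]) {
    kmin_lo <- kmin_hi <- 1L; p_lo <- 1
  } else if (k_avg >= means[k_max]) {
    kmin_lo <- kmin_hi <- k_max; p_lo <- 1
  } else {
    kmin_hi <- which(means >= k_avg)[1L]
    kmin_lo <- kmin_hi - 1L
    p_lo <- (means[kmin_hi] - k_avg) / (means[kmin_hi] - means[kmin_lo])
  }
  draw <- function(kmin, n) {
    if (n == 0L) return(integer(0))
    k <- kmin:k_max
    sample_vec(k, n, prob = k^(-t1))
  }
  use_lo <- stats::rbinom(N, 1L, p_lo) == 1L
  out <- integer(N)
  out[use_lo] <- draw(kmin_lo, sum(use_lo))
  out[!use_lo] <- draw(kmin_hi, sum(!use_lo))
  out
}

# Sample community sizes from a truncated power law s^-t2 on [C_min, C_max]
# whose total equals the required number of memberships; the tail is adjusted
# within bounds to hit the total exactly (or as closely as bounds allow).
sample_community_sizes <- function(total, t2, C_min, C_max) {
  s <- C_min:C_max
  w <- s^(-t2)
  sizes <- integer(0)
  while (sum(sizes) < total) {
    need <- total - sum(sizes)
    grab <- max(8L, ceiling(need / mean(s)))
    sizes <- c(sizes, sample_vec(s, grab, prob = w))
  }
  cum <- cumsum(sizes)
  sizes <- sizes[seq_len(which(cum >= total)[1L])]
  over <- sum(sizes) - total
  i <- length(sizes)
  while (over > 0L && i >= 1L) {  # trim overshoot within bounds
    take <- min(sizes[i] - C_min, over)
    sizes[i] <- sizes[i] - take
    over <- over - take
    i <- i - 1L
  }
  if (over > 0L) sizes <- sizes[-length(sizes)]  # bounds too tight: drop one
  sizes
}

# Pair stubs repeatedly, rejecting self-loops, duplicate edges (tracked in
# the hash environment `seen`), and (when `reject` is given) pairs failing
# the predicate. Persistent leftovers are resolved by double-edge swaps
# against the edges accepted in this call, the standard configuration-model
# rewiring repair; only truly unplaceable stubs are dropped.
match_stubs <- function(stubs, seen, reject = NULL, tries = 12L) {
  key_of <- function(a, b) paste(pmin(a, b), pmax(a, b))
  has <- function(k) exists(k, envir = seen, inherits = FALSE)
  eu <- integer(0); ev <- integer(0)
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
  for (t in seq_len(tries)) {
    if (length(stubs) < 2L) break
    stubs <- sample(stubs)
    half <- length(stubs) %/% 2L
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    key <- key_of(a, b)
    acc <- a != b & !duplicated(key) & !vapply(key, has, TRUE)
    if (!is.null(reject)) acc <- acc & !reject(a, b)
    for (k in key[acc]) assign(k, TRUE, envir = seen)
    eu <- c(eu, a[acc]); ev <- c(ev, b[acc])
    stubs <- c(a[!acc], b[!acc])
  }
  dropped <- 0L
  ok_pair <- function(a, b) {
    a != b && !has(key_of(a, b)) && (is.null(reject) || !reject(a, b))
  }
  while (length(stubs) >= 2L) {
    x <- stubs[1L]; y <- stubs[2L]; stubs <- stubs[-(1:2)]
    if (ok_pair(x, y)) {
      assign(key_of(x, y), TRUE, envir = seen)
      eu <- c(eu, x); ev <- c(ev, y)
      next
    }
    done <- FALSE
    if (length(eu)) for (attempt in 1:200) {
      j <- sample.int(length(eu), 1L)
      aa <- eu[j]; bb <- ev[j]
      if (aa %in% c(x, y) || bb %in% c(x, y)) next
      swapped <- if (ok_pair(x, aa) && ok_pair(y, bb)) c(aa, bb)
        else if (ok_pair(x, bb) && ok_pair(y, aa)) c(bb, aa)
        else NULL
      if (is.null(swapped)) next
      rm(list = key_of(aa, bb), envir = seen)
      assign(key_of(x, swapped[1L]), TRUE, envir = seen)
      assign(key_of(y, swapped[2L]), TRUE, envir = seen)
      eu[j] <- x; ev[j] <- swapped[1L]
      eu <- c(eu, y); ev <- c(ev, swapped[2L])
      done <- TRUE
      break
    }
    if (!done) dropped <- dropped + 2L
  }
  list(u = eu, v = ev, dropped = dropped + length(stubs))
}

#' Generate an LFR-style overlapping benchmark network
#'
#' Degrees are drawn from a truncated power law with exponent `t1`, mean
#' about `k_avg` and maximum `k_max`; community sizes from a truncated power
#' law with exponent `t2` on `[C_min, C_max]`. Exactly `round(On * N)` nodes
#' receive `Om` community memberships and the rest one. Each node splits its
#' degree into an intra-community budget `(1 - mu) * k` and an
#' inter-community budget `mu * k`; edges are realized by configuration-model
#' stub matching within each community and globally across communities, with
#' self-loops, multi-edges and same-community "inter" pairs rejected and
#' leftover stubs dropped.
#'
#' @param params A [benchmark_params()] object.
#' @return List with elements `network` (igraph, node ids 1..N), `cover`
#'   (the planted [community_cover()]), and `dropped_stubs` (count of
#'   unmatched half-edges).
#' @export
generate_benchmark <- function(params) {
  stopifnot(inherits(params, "benchmark_params"))
  p <- params
  n_over <- round(p$On * p$N)
  total_memb <- p$N + n_over * (p$Om - 1L)
  q_lo <- ceiling(total_memb / p$C_max)
  q_hi <- floor(total_memb / p$C_min)
  if (q_lo > q_hi)
    stop("infeasible parameters: no set of community sizes in [C_min, C_max] ",
         "can cover ", total_memb, " memberships")
  if (n_over > 0L && p$Om > q_hi)
    stop("infeasible parameters: Om exceeds the attainable number of communities")
  with_seed(p$seed, {
    degrees <- sample_power_degrees(p$N, p$t1, p$k_avg, p$k_max)
    sizes <- sample_community_sizes(total_memb, p$t2, p$C_min, p$C_max)
    q <- length(sizes)
    if (q < p$Om)
      stop("infeasible parameters: fewer communities than Om memberships per node")
    memb_count <- rep.int(1L, p$N)
    if (n_over > 0L) memb_count[sample.int(p$N, n_over)] <- p$Om
    intra_deg <- round((1 - p$mu) * degrees)
    # assign memberships greedily: high per-membership intra-degree nodes
    # first, into communities with room to host that intra degree
    per_memb <- ceiling(intra_deg / memb_count)
    ord <- order(per_memb, decreasing = TRUE)
    capacity <- sizes
    members <- vector("list", q)
    node_comms <- vector("list", p$N)
    for (v in ord) {
      need <- memb_count[v]
      feas <- which(capacity > 0L & sizes - 1L >= per_memb[v])
      if (length(feas) < need) feas <- which(capacity > 0L)
      if (length(feas) < need)
        feas <- utils::head(order(capacity, decreasing = TRUE), need)
      pick <- if (length(feas) == need) feas else
        feas[sample.int(length(feas), need, prob = capacity[feas] + 1e-9)]
      for (cm in pick) {
        members[[cm]] <- c(members[[cm]], v)
        capacity[cm] <- capacity[cm] - 1L
      }
      node_comms[[v]] <- pick
    }
    comm_size <- vapply(members, length, 1L)
    # the inter budget is fixed by mu; intra stubs a node's communities
    # cannot host are dropped rather than rerouted across communities
    inter_deg <- degrees - intra_deg
    host_room <- vapply(seq_len(p$N), function(v)
      sum(pmin(comm_size[node_comms[[v]]] - 1L, per_memb[v])), 0)
    dropped_cap <- sum(pmax(intra_deg - host_room, 0))
    intra_deg <- pmin(intra_deg, host_room)
    edge_u <- integer(0); edge_v <- integer(0)
    seen <- new.env(parent = emptyenv())
    dropped <- dropped_cap
    for (cm in seq_len(q)) {
      mem <- members[[cm]]
      if (length(mem) < 2L) next
      share <- vapply(mem, function(v) {
        s <- intra_deg[v] %/% memb_count[v]
        extra <- intra_deg[v] %% memb_count[v]
        as.integer(s + (match(cm, node_comms[[v]]) <= extra))
      }, 0L)
      share <- pmin(share, length(mem) - 1L)
      res <- match_stubs(rep.int(mem, share), seen)
      edge_u <- c(edge_u, res$u); edge_v <- c(edge_v, res$v)
      dropped <- dropped + res$dropped
    }
    # inter-community edges: reject pairs sharing any community
    share_comm <- function(a, b) vapply(seq_along(a), function(i)
      length(intersect(node_comms[[a[i]]], node_comms[[b[i]]])) > 0L, TRUE)
    res <- match_stubs(rep.int(seq_len(p$N), inter_deg), seen,
                       reject = share_comm, tries = 8L)
    edge_u <- c(edge_u, res$u); edge_v <- c(edge_v, res$v)
    dropped <- dropped + res$dropped
    network <- build_network(cbind(edge_u, edge_v), nodes = seq_len(p$N))
    cover <- community_cover(members[comm_size > 0L])
    list(network = network, cover = cover, dropped_stubs = dropped)
  })
}

#' Empirical mixing fraction of a network given a cover
#'
#' Fraction of edges joining nodes that share no community, i.e. the realized
#' counterpart of the mixing parameter `mu`.
#'
#' @param network igraph graph.
#' @param cover [community_cover()].
#' @return Mixing fraction in \[0, 1\].
#' @export
measured_mixing <- function(network, cover) {
  el <- igraph::as_edgelist(network, names = TRUE)
  u <- as.integer(el[, 1L]); v <- as.integer(el[, 2L])
  idx <- membership_index(cover)
  inter <- vapply(seq_along(u), function(i) {
    cu <- idx[[as.character(u[i])]]; cv <- idx[[as.character(v[i])]]
    is.null(cu) || is.null(cv) || !length(intersect(cu, cv))
  }, TRUE)
  sum(inter) / length(inter)
}
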
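#' Construct a constraint set
#'
#' A constraint set is a data frame with one row per unordered node pair and
#' columns `u`, `v` (integer ids, u < v), `observed` and `true` labels
#' (`"ML"` or `"CL"`), and the logical `noisy` flag
#' (`noisy == (observed != true)`).
#'
#' @param u,v Integer node ids (vectors of equal length).
#' @param observed,true Character labels, `"ML"` or `"CL"`.
#' @return A `constraint_set` data frame.
#' @export
constraint_set <- function(u = integer(0), v = integer(0),
                           observed = character(0), true = observed) {
  u <- as.integer(u); v <- as.integer(v)
  if (any(u == v)) stop("self-pair constraint not allowed")
  lo <- pmin(u, v); hi <- pmax(u, v)
  if (anyDuplicated(paste(lo, hi))) stop("duplicate constraint pair")
  if (!all(observed %in% c("ML", "CL")) || !all(true %in% c("ML", "CL")))
    stop("labels must be \"ML\" or \"CL\"")
  structure(
    data.frame(u = lo, v = hi, observed = observed, true = true,
               noisy = observed != true, stringsAsFactors = FALSE),
    class = c("constraint_set", "data.frame"))
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("constraint set:", nrow(x), "pairs (",
      sum(x$observed == "ML"), "ML /", sum(x$observed == "CL"), "CL ),",
      sum(x$noisy), "noisy\n")
  invisible(x)
}

# node id -> indices of communities containing it
membership_index <- function(cover) {
  ids <- unlist(cover, use.names = FALSE)
  ci <- rep.int(seq_along(cover), vapply(cover, length, 1L))
  split(ci, ids)
}

#' Ground-truth label of a node pair under a cover
#'
#' `"ML"` iff the two nodes share at least one community, else `"CL"`.
#' Overlap-aware: an overlapping node can be must-linked with members of all
#' its communities, and the must-link relation is not transitive on covers
#' with overlap.
#'
#' @param u,v Distinct node ids present in `cover`.
#' @param cover A [community_cover()].
#' @return `"ML"` or `"CL"`.
#' @export
#' @examples
#' cov <- community_cover(list(c(1, 2), c(2, 3)))
#' true_label(1, 2, cov) # "ML"
#' true_label(1, 3, cov) # "CL" despite 1-2 and 2-3 being ML
true_label <- function(u, v, cover) {
  if (u == v) stop("u and v must differ")
  idx <- membership_index(cover)
  cu <- idx[[as.character(u)]]; cv <- idx[[as.character(v)]]
  if (is.null(cu)) stop("node ", u, " absent from cover")
  if (is.null(cv)) stop("node ", v, " absent from cover")
  if (length(intersect(cu, cv))) "ML" else "CL"
}

#' Label node pairs from a ground-truth cover (perfect oracle)
#'
#' @param pairs Two-column integer matrix of node pairs (distinct, no
#'   self-pairs).
#' @param cover A [community_cover()].
#' @return A [constraint_set()] with `observed == true` and no noise.
#' @export
annotate_pairs <- function(pairs, cover) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  if (nrow(pairs) == 0L) return(constraint_set())
  if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pair in input")
  lo <- pmin(pairs[, 1L], pairs[, 2L]); hi <- pmax(pairs[, 1L], pairs[, 2L])
  if (anyDuplicated(paste(lo, hi))) stop("duplicate pair in input")
  idx <- membership_index(cover)
  lab <- vapply(seq_along(lo), function(i) {
    cu <- idx[[as.character(lo[i])]]; cv <- idx[[as.character(hi[i])]]
    if (is.null(cu) || is.null(cv))
      stop("pair (", lo[i], ", ", hi[i], ") has a node absent from cover")
    if (length(intersect(cu, cv))) "ML" else "CL"
  }, "")
  constraint_set(lo, hi, lab, lab)
}

#' Inject label-flip noise into a constraint set
#'
#' Flips the observed labels of exactly
#' `k = round(rate * min(|ML|, |CL|))` constraints (round half up; at least 1
#' when `rate > 0` and the smaller view is non-empty), sampled uniformly
#' without replacement from the union of both views. Flipped constraints move
#' to the opposite observed view and are marked noisy.
#'
#' @param cs A [constraint_set()].
#' @param rate Noise level as a fraction of the smaller constraint view
#'   (the convention used throughout: 0.1 = "10% of the smallest set").
#' @param seed Integer seed for reproducible sampling.
#' @return The constraint set with flipped labels.
#' @export
inject_noise <- function(cs, rate = 0.1, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  n_ml <- sum(cs$observed == "ML"); n_cl <- sum(cs$observed == "CL")
  k <- floor(rate * min(n_ml, n_cl) + 0.5)
  if (rate > 0 && min(n_ml, n_cl) > 0L && k == 0L) k <- 1L
  if (k == 0L) {
    warning("no labels flipped (k = 0); constraint set returned unchanged")
    return(cs)
  }
  flip <- with_seed(seed, sample.int(nrow(cs), k))
  cs$observed[flip] <- ifelse(cs$observed[flip] == "ML", "CL", "ML")
  cs$noisy <- cs$observed != cs$true
  cs
}

#' Write / read a constraint set as TSV
#'
#' Columns: `u  v  observed  true  noisy`.
#'
#' @param cs A [constraint_set()].
#' @param path File path.
#' @return `path` (write) or the constraint set (read).
#' @export
write_constraints <- function(cs, path) {
  utils::write.table(as.data.frame(cs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  constraint_set(d$u, d$v, d$observed, d$true)
}
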
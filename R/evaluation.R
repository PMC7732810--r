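#' ROC-AUC of an outlier score against binary truth
#'
#' Rank-statistic formulation: the probability that a uniformly chosen
#' positive (noisy) example outscores a uniformly chosen negative one, with
#' ties counted half.
#'
#' @param scores Numeric scores (higher = more likely noisy).
#' @param truth Logical or 0/1 vector of the same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_entropy_terms <- function(p) {
  # -p log2 p with the 0 log 0 = 0 convention
  ifelse(p > 0, -p * log2(p), 0)
}

#' Overlapping normalized mutual information between two covers
#'
#' Each community is treated as a binary node-membership vector. Community-
#' to-community conditional entropies are computed with the zero-entropy
#' guard (a candidate match is only admissible when
#' `h(p11) + h(p00) >= h(p01) + h(p10)`; otherwise conditioning provides no
#' information and the unconditional entropy is used). The aggregate mutual
#' information is normalized by `max(H(A), H(B))`, so identical covers score
#' 1 and unrelated covers score about 0.
#'
#' @param cover_a,cover_b [community_cover()] objects over the same node
#'   universe.
#' @param nodes Optional explicit node universe (integer ids); defaults to
#'   the union of both covers' nodes.
#' @return ONMI in \[0, 1\].
#' @export
overlapping_nmi <- function(cover_a, cover_b, nodes = NULL) {
  na_ <- unique(unlist(cover_a)); nb_ <- unique(unlist(cover_b))
  if (!length(intersect(na_, nb_)))
    stop("covers have disjoint node universes")
  nodes <- nodes %||% sort(unique(c(na_, nb_)))
  n <- length(nodes)
  memb <- function(cover) {
    m <- matrix(FALSE, length(cover), n)
    for (i in seq_along(cover)) m[i, match(cover[[i]], nodes)] <- TRUE
    m
  }
  A <- memb(cover_a); B <- memb(cover_b)
  h2 <- function(p) binary_entropy_terms(p) + binary_entropy_terms(1 - p)
  HA <- h2(rowSums(A) / n)   # per-community marginal entropies
  HB <- h2(rowSums(B) / n)
  # conditional entropy of each community of X given the best admissible
  # community of Y
  cond <- function(X, HX, Y, HY) {
    n11 <- X %*% t(Y)                      # |Xk & Yl|
    kx <- rowSums(X)
    ly <- rowSums(Y)
    vapply(seq_len(nrow(X)), function(k) {
      p11 <- n11[k, ] / n
      p10 <- (kx[k] - n11[k, ]) / n
      p01 <- (ly - n11[k, ]) / n
      p00 <- 1 - p11 - p10 - p01
      ok <- binary_entropy_terms(p11) + binary_entropy_terms(p00) >=
        binary_entropy_terms(p01) + binary_entropy_terms(p10)
      joint <- binary_entropy_terms(p11) + binary_entropy_terms(p10) +
        binary_entropy_terms(p01) + binary_entropy_terms(p00)
      hc <- joint - HY
      if (any(ok)) min(hc[ok], HX[k]) else HX[k]
    }, 0)
  }
  HAgB <- cond(A, HA, B, HB)
  HBgA <- cond(B, HB, A, HA)
  I <- 0.5 * (sum(HA - HAgB) + sum(HB - HBgA))
  denom <- max(sum(HA), sum(HB))
  if (denom == 0) return(1)  # both covers carry no information: identical
  max(0, min(1, I / denom))
}

#' Two-sample Kolmogorov-Smirnov comparison of community-size samples
#'
#' @param sizes_a,sizes_b Non-empty numeric samples (community sizes).
#' @return List with elements `D` (max ECDF distance) and `p` (asymptotic
#'   p-value).
#' @export
ks_two_sample <- function(sizes_a, sizes_b) {
  if (!length(sizes_a) || !length(sizes_b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(sizes_a, sizes_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Average ranks of algorithms over networks
#'
#' Ranks algorithms within each network (1 = best, ties share the mean rank),
#' then averages per algorithm.
#'
#' @param score_table Numeric matrix, algorithms in rows, networks in columns.
#' @param higher_is_better Direction of the scores (default TRUE).
#' @return Named numeric vector of mean ranks.
#' @export
average_ranks <- function(score_table, higher_is_better = TRUE) {
  score_table <- as.matrix(score_table)
  if (anyNA(score_table)) stop("score table has missing cells")
  ranks <- apply(score_table, 2L, function(col)
    rank(if (higher_is_better) -col else col, ties.method = "average"))
  out <- rowMeans(ranks)
  names(out) <- rownames(score_table)
  out
}
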
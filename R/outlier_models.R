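#' Specify a traditional outlier detector
#'
#' @param family `"isolation_forest"`, `"ocsvm"`, or `"lof"`.
#' @param contamination Assumed outlier fraction used to set the flagging
#'   threshold for score-based families (isolation forest, LOF).
#' @param nu OCSVM margin parameter.
#' @param k LOF neighborhood size.
#' @param n_trees Isolation forest ensemble size.
#' @param sample_size Isolation forest subsample size per tree.
#' @return An `outlier_model_spec`.
#' @export
detector_spec <- function(family = c("isolation_forest", "ocsvm", "lof"),
                          contamination = 0.1, nu = 0.5, k = 20L,
                          n_trees = 100L, sample_size = 256L) {
  family <- match.arg(family)
  stopifnot(contamination > 0, contamination < 0.5)
  structure(list(family = family, contamination = contamination, nu = nu,
                 k = as.integer(k), n_trees = as.integer(n_trees),
                 sample_size = as.integer(sample_size)),
            class = "outlier_model_spec")
}

# ---- isolation forest -----------------------------------------------------

# average unsuccessful-search path length in a BST of n points
avg_path_length <- function(n) {
  ifelse(n > 2, 2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n,
         ifelse(n == 2, 1, 0))
}

grow_itree <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1L || depth >= max_depth)
    return(list(leaf = TRUE, size = n))
  spans <- apply(X[idx, , drop = FALSE], 2L, function(c) range(c))
  varying <- which(spans[2L, ] > spans[1L, ])
  if (!length(varying)) return(list(leaf = TRUE, size = n))
  f <- varying[sample.int(length(varying), 1L)]
  cut <- stats::runif(1L, spans[1L, f], spans[2L, f])
  left <- idx[X[idx, f] < cut]
  right <- idx[X[idx, f] >= cut]
  if (!length(left) || !length(right)) return(list(leaf = TRUE, size = n))
  list(leaf = FALSE, feature = f, cut = cut,
       left = grow_itree(X, left, depth + 1L, max_depth),
       right = grow_itree(X, right, depth + 1L, max_depth))
}

fit_isolation_forest <- function(X, n_trees = 100L, sample_size = 256L,
                                 seed = NULL) {
  X <- as.matrix(X)
  psi <- min(sample_size, nrow(X))
  max_depth <- ceiling(log2(psi))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(i)
    grow_itree(X, sample.int(nrow(X), psi), 0L, max_depth)))
  structure(list(trees = trees, psi = psi), class = "isolation_forest")
}

# anomaly score 2^(-E[h]/c(psi)); close to 1 = anomalous
score_isolation_forest <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  htot <- numeric(n)
  walk <- function(tree, idx, depth) {
    if (tree$leaf) {
      htot[idx] <<- htot[idx] + depth + avg_path_length(tree$size)
      return(invisible(NULL))
    }
    gl <- X[idx, tree$feature] < tree$cut
    if (any(gl)) walk(tree$left, idx[gl], depth + 1)
    if (!all(gl)) walk(tree$right, idx[!gl], depth + 1)
    invisible(NULL)
  }
  for (tr in model$trees) walk(tr, seq_len(n), 0)
  2^(-(htot / length(model$trees)) / avg_path_length(model$psi))
}

# ---- local outlier factor -------------------------------------------------

# LOF of every row of X with neighborhood size k; duplicated points (zero
# local reachability) are handled by the usual Inf/Inf -> 1 convention.
lof_scores <- function(X, k = 20L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- min(k, n - 1L)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  kdist <- apply(D, 1L, function(d) sort(d)[k])
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= kdist[i]))
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[nbrs[[i]]], D[i, nbrs[[i]]])
    1 / mean(reach)
  }, 0)
  vapply(seq_len(n), function(i) {
    r <- mean(lrd[nbrs[[i]]]) / lrd[i]
    if (is.nan(r)) 1 else r
  }, 0)
}

# ---- dispatch -------------------------------------------------------------

#' Fit an outlier detector and flag outlying rows
#'
#' Fits the requested family on `X` and returns per-row outlier flags along
#' with a continuous anomaly score (higher = more outlying). For the
#' score-threshold families (isolation forest, LOF) the flagged fraction
#' equals the contamination setting; the OCSVM flags follow the sign of its
#' decision function.
#'
#' @param spec A [detector_spec()].
#' @param X Numeric matrix (rows = constraints, columns = features).
#' @param seed Seed for the stochastic families.
#' @return List with `model`, logical `flags`, and numeric `scores`.
#' @export
fit_and_flag <- function(spec, X, seed = NULL) {
  stopifnot(inherits(spec, "outlier_model_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  min_rows <- if (spec$family == "lof") max(10L, spec$k + 1L) else 10L
  if (n < min_rows)
    stop("too few rows (", n, ") to fit an outlier detector; ",
         "accumulate more constraints (need >= ", min_rows, ")")
  if (spec$family == "isolation_forest") {
    model <- fit_isolation_forest(X, spec$n_trees, spec$sample_size, seed)
    scores <- score_isolation_forest(model, X)
    flags <- flag_top(scores, spec$contamination)
  } else if (spec$family == "lof") {
    model <- list(k = spec$k)
    scores <- lof_scores(X, spec$k)
    flags <- flag_top(scores, spec$contamination)
  } else {
    model <- with_seed(seed, e1071::svm(X, y = NULL,
                                        type = "one-classification",
                                        kernel = "radial", nu = spec$nu,
                                        scale = FALSE))
    pred <- stats::predict(model, X, decision.values = TRUE)
    scores <- -as.numeric(attr(pred, "decision.values"))
    flags <- !as.logical(pred)
  }
  list(model = model, flags = flags, scores = scores)
}

# flag the round(frac * n) highest scores; stable ties by original index
flag_top <- function(scores, frac) {
  n <- length(scores)
  k <- round(frac * n)
  flags <- rep(FALSE, n)
  if (k > 0L) flags[order(-scores, seq_len(n))[seq_len(k)]] <- TRUE
  flags
}

# ---- autoencoders ---------------------------------------------------------

#' Autoencoder architecture
#'
#' Layer widths must be symmetric with first = last = input dimensionality.
#' The six standard architectures are available by name via
#' [ae_architecture()].
#'
#' @param dims Integer vector of layer widths, e.g. `c(7, 3, 7)`.
#' @param l1 Sparsity weight on the bottleneck activations (0 = none).
#' @param epochs Training epochs.
#' @param lr Learning rate for plain mini-batch gradient descent.
#' @param batch_size Mini-batch size.
#' @return An `ae_architecture` list.
#' @export
ae_spec <- function(dims, l1 = 0, epochs = 100L, lr = 0.01,
                    batch_size = 256L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) >= 2L, dims[1L] == dims[length(dims)],
            all(dims == rev(dims)), l1 >= 0, lr > 0, epochs >= 1L)
  structure(list(dims = dims, l1 = l1, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "ae_architecture")
}

#' Standard autoencoder architectures
#'
#' `AE1` (7,3,7), `AE2` (7,5,3,5,7) and `AE3` (7,6,5,3,5,6,7) compress
#' towards a bottleneck; their `_L1` counterparts keep constant width 7 and
#' add an L1 penalty of 1e-3 on the bottleneck activations. The training
#' regime depends on the network scale: 100 epochs at learning rate 0.01 for
#' small networks, 30 epochs at 0.001 for large ones, batch size 256
#' throughout.
#'
#' @param name One of `"AE1"`, `"AE1_L1"`, `"AE2"`, `"AE2_L1"`, `"AE3"`,
#'   `"AE3_L1"`.
#' @param scale `"small"` or `"large"` training regime.
#' @return An [ae_spec()].
#' @export
ae_architecture <- function(name, scale = c("small", "large")) {
  scale <- match.arg(scale)
  dims <- switch(name,
    AE1 = c(7, 3, 7),
    AE1_L1 = c(7, 7, 7),
    AE2 = c(7, 5, 3, 5, 7),
    AE2_L1 = c(7, 7, 7, 7, 7),
    AE3 = c(7, 6, 5, 3, 5, 6, 7),
    AE3_L1 = c(7, 7, 7, 7, 7, 7, 7),
    stop("unknown architecture: ", name))
  l1 <- if (grepl("_L1$", name)) 1e-3 else 0
  if (scale == "small") ae_spec(dims, l1, epochs = 100L, lr = 0.01)
  else ae_spec(dims, l1, epochs = 30L, lr = 0.001)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

ae_forward <- function(model, X) {
  L <- length(model$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% model$W[[l]] +
      matrix(model$b[[l]], nrow(X), length(model$b[[l]]), byrow = TRUE)
    acts[[l + 1L]] <- if (l < L) relu(z) else sigmoid(z)
  }
  acts
}

#' Train an autoencoder by plain mini-batch gradient descent
#'
#' Minimizes the mean squared reconstruction error, plus an L1 penalty on
#' the bottleneck activations when the architecture's sparsity weight is
#' positive. Hidden layers use rectifier activations; the output layer is
#' logistic (inputs are expected scaled to \[0, 1\]). Weight initialization
#' and batch order are reproducible from `seed`. The per-epoch loss trace is
#' kept on the model; a warning is raised when the loss trend over training
#' increases.
#'
#' @param arch An [ae_spec()] / [ae_architecture()].
#' @param X Numeric matrix with `ncol(X) == arch$dims[1]`, scaled to
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return A `trained_autoencoder` with weights, the architecture, and the
#'   loss trace.
#' @export
train_autoencoder <- function(arch, X, seed = NULL) {
  stopifnot(inherits(arch, "ae_architecture"))
  X <- as.matrix(X)
  if (ncol(X) != arch$dims[1L])
    stop("input dimensionality ", ncol(X), " does not match architecture (",
         arch$dims[1L], ")")
  dims <- arch$dims
  L <- length(dims) - 1L
  bottleneck <- (length(dims) + 1L) %/% 2L  # index into activation list
  with_seed(seed, {
    model <- list(
      W = lapply(seq_len(L), function(l) {
        a <- sqrt(6 / (dims[l] + dims[l + 1L]))
        matrix(stats::runif(dims[l] * dims[l + 1L], -a, a),
               dims[l], dims[l + 1L])
      }),
      b = lapply(seq_len(L), function(l) numeric(dims[l + 1L])),
      arch = arch, bottleneck = bottleneck)
    n <- nrow(X)
    losses <- numeric(arch$epochs)
    for (ep in seq_len(arch$epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / arch$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        xb <- X[bt, , drop = FALSE]
        m <- nrow(xb)
        acts <- ae_forward(model, xb)
        out <- acts[[L + 1L]]
        err <- out - xb
        mse <- mean(err^2)
        if (!is.finite(mse))
          stop("non-finite training loss at epoch ", ep)
        h <- acts[[bottleneck]]
        ep_loss <- ep_loss + (mse + arch$l1 * mean(rowSums(abs(h)))) * m
        # backprop: output layer is logistic with squared-error loss
        delta <- (2 * err / ncol(xb) / m) * out * (1 - out)
        for (l in L:1) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            back <- delta %*% t(model$W[[l]])
            if (arch$l1 > 0 && l == bottleneck)
              back <- back + arch$l1 * sign(acts[[l]]) / m
            delta <- back * (acts[[l]] > 0)
          }
          model$W[[l]] <- model$W[[l]] - arch$lr * gW
          model$b[[l]] <- model$b[[l]] - arch$lr * gb
        }
      }
      losses[ep] <- ep_loss / n
    }
    tenth <- max(1L, arch$epochs %/% 10L)
    if (mean(tail(losses, tenth)) > mean(head(losses, tenth)) * 1.05)
      warning("autoencoder training loss increased over training")
    model$losses <- losses
    class(model) <- "trained_autoencoder"
    model
  })
}

#' Reconstruct inputs and report per-row mean squared error
#'
#' @param model A [train_autoencoder()] fit.
#' @param X Matrix with the training dimensionality.
#' @return Numeric vector of per-row reconstruction errors (>= 0); large
#'   errors indicate outliers.
#' @export
reconstruction_errors <- function(model, X) {
  X <- as.matrix(X)
  acts <- ae_forward(model, X)
  rowMeans((acts[[length(acts)]] - X)^2)
}

#' Bottleneck representation of the inputs
#'
#' Applies only the encoder half of a trained autoencoder, for use as a
#' learned embedding feeding a traditional outlier detector.
#'
#' @inheritParams reconstruction_errors
#' @return Matrix of bottleneck activations.
#' @export
encode_latent <- function(model, X) {
  X <- as.matrix(X)
  acts <- ae_forward(model, X)
  acts[[model$bottleneck]]
}

#' Keep the lowest-error rows
#'
#' Keeps the `ceiling(keep_fraction * n)` rows with the smallest
#' reconstruction error; ties at the cut boundary are broken by the lower
#' original index.
#'
#' @param errors Per-row errors.
#' @param keep_fraction Fraction of rows to keep, in (0, 1].
#' @return Logical keep mask.
#' @export
select_clean_by_error <- function(errors, keep_fraction = 0.9) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  n <- length(errors)
  if (n == 0L) return(logical(0))
  k <- ceiling(keep_fraction * n)
  keep <- rep(FALSE, n)
  keep[order(errors, seq_len(n))[seq_len(k)]] <- TRUE
  keep
}
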
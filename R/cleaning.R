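#' Model choice for one constraint view
#'
#' A view model is either a traditional detector ([detector_spec()]), an
#' autoencoder used through its reconstruction error ([ae_spec()] /
#' [ae_architecture()]), or an encoder + detector pair built with this
#' helper.
#'
#' @param encoder An [ae_spec()] whose bottleneck feeds the detector.
#' @param detector A [detector_spec()] applied to the bottleneck codes.
#' @return An `encoder_detector` pairing.
#' @export
encoder_detector <- function(encoder, detector) {
  stopifnot(inherits(encoder, "ae_architecture"),
            inherits(detector, "outlier_model_spec"))
  structure(list(encoder = encoder, detector = detector),
            class = "encoder_detector")
}

#' Configuration of the constraint-cleaning process
#'
#' @param category One of `"traditional"`, `"deep_embedding"`,
#'   `"autoencoder"`, `"hybrid"` (informational label; the behavior is set
#'   by the two view models).
#' @param ml_model,cl_model View model for the must-link / cannot-link view:
#'   a [detector_spec()], an [ae_spec()], or an [encoder_detector()].
#' @param sub_iterations Cleaning rounds per view; the model is refit on the
#'   surviving rows each round.
#' @param keep_fraction Fraction of lowest-error rows kept per round by
#'   reconstruction-error models.
#' @return A `cleaning_config`.
#' @export
cleaning_config <- function(category, ml_model, cl_model,
                            sub_iterations = 2L, keep_fraction = 0.9) {
  stopifnot(sub_iterations >= 1L, keep_fraction > 0, keep_fraction <= 1)
  structure(list(category = category, ml_model = ml_model,
                 cl_model = cl_model,
                 sub_iterations = as.integer(sub_iterations),
                 keep_fraction = keep_fraction),
            class = "cleaning_config")
}

#' Network-scale regime used to pick architectures and training schedules
#'
#' @param network igraph graph.
#' @return `"small"` (fewer than 2500 nodes) or `"large"`.
#' @export
network_scale <- function(network) {
  if (igraph::vcount(network) < 2500L) "small" else "large"
}

#' Default cleaning configurations per category and network scale
#'
#' The model pairings follow the best performers per category: the hybrid
#' process cleans must-links with a sparse autoencoder (AE1_L1 small /
#' AE2_L1 large) and cannot-links with the AE3 encoder feeding an isolation
#' forest; the pure autoencoder process uses AE3_L1 on cannot-links; the
#' deep-embedding process pairs unconstrained encoders with one-class SVM
#' (must-link) and isolation forest (cannot-link); the traditional process
#' uses one-class SVM and isolation forest directly.
#'
#' @param scale `"small"` or `"large"` (see [network_scale()]).
#' @param category Cleaning category.
#' @return A [cleaning_config()].
#' @export
default_config <- function(scale = c("small", "large"),
                           category = c("hybrid", "autoencoder",
                                        "deep_embedding", "traditional")) {
  scale <- match.arg(scale)
  category <- match.arg(category)
  ifsp <- detector_spec("isolation_forest")
  svmsp <- detector_spec("ocsvm")
  enc_if <- encoder_detector(ae_architecture("AE3", scale), ifsp)
  ml <- switch(category,
    hybrid = ae_architecture(if (scale == "small") "AE1_L1" else "AE2_L1",
                             scale),
    autoencoder = ae_architecture(if (scale == "small") "AE1_L1" else
                                  "AE2_L1", scale),
    deep_embedding = encoder_detector(
      ae_architecture(if (scale == "small") "AE3" else "AE2", scale), svmsp),
    traditional = svmsp)
  cl <- switch(category,
    hybrid = enc_if,
    autoencoder = ae_architecture("AE3_L1", scale),
    deep_embedding = enc_if,
    traditional = ifsp)
  cleaning_config(category, ml, cl)
}

# Smallest view a model can be fit on.
min_rows_for <- function(model) {
  if (inherits(model, "outlier_model_spec") && model$family == "lof")
    max(10L, model$k + 1L)
  else if (inherits(model, "encoder_detector")) min_rows_for(model$detector)
  else 10L
}

# Fit a view model on X; returns keep mask and anomaly scores.
apply_view_model <- function(model, X, keep_fraction, seed = NULL) {
  if (inherits(model, "outlier_model_spec")) {
    ff <- fit_and_flag(model, X, seed)
    list(keep = !ff$flags, scores = ff$scores)
  } else if (inherits(model, "ae_architecture")) {
    fit <- train_autoencoder(model, X, seed)
    errs <- reconstruction_errors(fit, X)
    list(keep = select_clean_by_error(errs, keep_fraction), scores = errs)
  } else if (inherits(model, "encoder_detector")) {
    fit <- train_autoencoder(model$encoder, X, seed)
    latent <- encode_latent(fit, X)
    ff <- fit_and_flag(model$detector, latent, seed)
    list(keep = !ff$flags, scores = ff$scores)
  } else stop("unknown view model")
}

#' Clean a constraint set by per-view outlier removal
#'
#' Extracts the 7-dimensional pair features, then runs `sub_iterations`
#' rounds per observed view (must-link and cannot-link separately): fit the
#' view's model on the surviving rows, flag outliers (detector flags, or the
#' reconstruction-error cut at `keep_fraction`), remove them, refit. A view
#' too small to fit a model passes through uncleaned with a warning.
#'
#' @param cs A [constraint_set()].
#' @param network igraph graph.
#' @param config A [cleaning_config()].
#' @param seed Integer seed.
#' @param cache Optional [feature_cache()].
#' @return List with `kept` and `discarded` constraint sets (a partition of
#'   `cs`) and a `log` data frame of per-round removal counts.
#' @export
clean_constraint_set <- function(cs, network, config, seed = NULL,
                                 cache = NULL) {
  stopifnot(inherits(config, "cleaning_config"))
  if (!nrow(cs)) stop("constraint set is empty")
  fm <- extract_features(cs, network, cache)
  log <- list()
  surviving_all <- logical(nrow(cs))
  for (view in c("ML", "CL")) {
    idx <- which(cs$observed == view)
    model <- if (view == "ML") config$ml_model else config$cl_model
    min_rows <- min_rows_for(model)
    if (length(idx) < min_rows) {
      if (length(idx))
        warning(view, " view too small to clean (", length(idx),
                " rows); passed through")
      surviving_all[idx] <- TRUE
      next
    }
    surv <- idx
    for (it in seq_len(config$sub_iterations)) {
      if (length(surv) < min_rows) break
      res <- apply_view_model(model, fm$scaled[surv, , drop = FALSE],
                              config$keep_fraction,
                              child_seed(seed, it * 17L +
                                           (view == "CL") * 7001L))
      log[[length(log) + 1L]] <- data.frame(
        view = view, round = it, fitted = length(surv),
        removed = sum(!res$keep))
      surv <- surv[res$keep]
    }
    surviving_all[surv] <- TRUE
  }
  list(kept = cs[surviving_all, , drop = FALSE],
       discarded = cs[!surviving_all, , drop = FALSE],
       log = do.call(rbind, log) %||%
         data.frame(view = character(0), round = integer(0),
                    fitted = integer(0), removed = integer(0)))
}

#' Recheck discarded constraints to recover mislabelled non-noise
#'
#' Re-runs the cleaning process on the discarded pool; rows surviving all
#' rounds are returned for merging back into the kept set, reducing wastage
#' of the annotation budget.
#'
#' @inheritParams clean_constraint_set
#' @param discarded Constraint set previously discarded by cleaning.
#' @return The recovered constraint set (a subset of `discarded`).
#' @export
recheck_discarded <- function(discarded, network, config, seed = NULL,
                              cache = NULL) {
  if (!nrow(discarded)) return(discarded)
  clean_constraint_set(discarded, network, config, seed, cache)$kept
}

#' Continuous noise scores for each view of a constraint set
#'
#' Fits the view model once on the full view and returns its anomaly score
#' per row (reconstruction error for autoencoders, detector score
#' otherwise), for threshold-free evaluation such as ROC-AUC against the
#' hidden noise flags.
#'
#' @inheritParams clean_constraint_set
#' @param fm Optional precomputed [extract_features()] result for `cs`.
#' @return List with per-view data frames (`index`, `score`, `noisy`).
#' @export
view_noise_scores <- function(cs, network, config, seed = NULL, cache = NULL,
                              fm = NULL) {
  fm <- fm %||% extract_features(cs, network, cache)
  out <- list()
  for (view in c("ML", "CL")) {
    idx <- which(cs$observed == view)
    if (length(idx) < 10L) next
    model <- if (view == "ML") config$ml_model else config$cl_model
    res <- apply_view_model(model, fm$scaled[idx, , drop = FALSE], 1,
                            child_seed(seed, (view == "CL") * 7001L))
    out[[view]] <- data.frame(index = idx, score = res$scores,
                              noisy = cs$noisy[idx])
  }
  out
}
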
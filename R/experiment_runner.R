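#' Per-view noise-detection AUC of a model on a constraint set
#'
#' Trains the given model on each observed view of the constraint set and
#' scores every row (reconstruction error for autoencoders, anomaly score
#' for detectors), then computes the ROC-AUC of the scores against the
#' hidden noise flags. A view with fewer than 10 rows, or with only one
#' class present, yields `NA`.
#'
#' @param cs A noisy [constraint_set()].
#' @param network igraph graph.
#' @param model A view model: [ae_spec()], [detector_spec()], or
#'   [encoder_detector()].
#' @param seed Integer seed.
#' @param cache Optional [feature_cache()].
#' @param fm Optional precomputed [extract_features()] result.
#' @param views Which observed views to score (default both).
#' @return Named numeric vector `c(ML = ..., CL = ...)`.
#' @export
constraint_noise_auc <- function(cs, network, model, seed = NULL,
                                 cache = NULL, fm = NULL,
                                 views = c("ML", "CL")) {
  fm <- fm %||% extract_features(cs, network, cache)
  out <- c(ML = NA_real_, CL = NA_real_)
  for (view in views) {
    idx <- which(cs$observed == view)
    if (length(idx) < 10L) next
    flags <- cs$noisy[idx]
    if (length(unique(flags)) < 2L) next
    res <- apply_view_model(model, fm$scaled[idx, , drop = FALSE], 1,
                            child_seed(seed, (view == "CL") * 7001L))
    out[view] <- roc_auc(res$scores, flags)
  }
  out
}

#' Configuration for a benchmark evaluation suite
#'
#' @param grid Data frame of benchmark cells with columns `N`, `mu`, `On`,
#'   `Om`, `C_min`, `C_max` (one row per network).
#' @param seeds_per_cell Replicate seeds per cell.
#' @param noise_rate Oracle label-flip level.
#' @param detector_models Named list of view models evaluated in the
#'   detector-AUC experiment (`NULL` skips it).
#' @param variants Character vector of end-to-end variants to run, from
#'   `"slpa"`, `"acslpa_noclean"`, `"hybrid"`, `"autoencoder"`,
#'   `"deep_embedding"`, `"traditional"` (`NULL` skips the end-to-end
#'   experiment).
#' @param iterations,total_budget Active-loop settings.
#' @param slpa [slpa_params()] template.
#' @param seed Master seed.
#' @return A `suite_config`.
#' @export
suite_config <- function(grid, seeds_per_cell = 1L, noise_rate = 0.1,
                         detector_models = NULL, variants = c("slpa"),
                         iterations = 10L, total_budget = NULL,
                         slpa = slpa_params(), seed = 1L) {
  stopifnot(nrow(grid) >= 1L, seeds_per_cell >= 1L)
  structure(list(grid = grid, seeds_per_cell = as.integer(seeds_per_cell),
                 noise_rate = noise_rate,
                 detector_models = detector_models, variants = variants,
                 iterations = as.integer(iterations),
                 total_budget = total_budget, slpa = slpa,
                 seed = as.integer(seed)),
            class = "suite_config")
}

#' Standard benchmark grids
#'
#' `"small"`: N = 1000 with community sizes 10-50; `"large"`: N = 5000 with
#' sizes 20-100; both cross mixing 0.1/0.3, overlap fraction 10%/50%, and
#' the requested memberships-per-overlapping-node values.
#'
#' @param regime `"small"` or `"large"`.
#' @param mu,On,Om Parameter values crossed into the grid.
#' @return A data frame suitable for [suite_config()].
#' @export
benchmark_grid <- function(regime = c("small", "large"),
                           mu = c(0.1, 0.3), On = c(0.1, 0.5),
                           Om = c(2L, 8L)) {
  regime <- match.arg(regime)
  g <- expand.grid(mu = mu, On = On, Om = Om)
  g$N <- if (regime == "small") 1000L else 5000L
  g$C_min <- if (regime == "small") 10L else 20L
  g$C_max <- if (regime == "small") 50L else 100L
  g
}

run_suite_cell <- function(cell, rep_seed, cfg) {
  params <- benchmark_params(N = cell$N, mu = cell$mu, On = cell$On,
                             Om = cell$Om, C_min = cell$C_min,
                             C_max = cell$C_max, seed = rep_seed)
  bench <- generate_benchmark(params)
  g <- bench$network; gt <- bench$cover
  scale <- network_scale(g)
  rows <- list()
  emit <- function(metric, value, model) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, value = value, model = model, N = cell$N,
      mu = cell$mu, On = cell$On, Om = cell$Om, seed = rep_seed)
  }
  needs_features <- !is.null(cfg$detector_models) ||
    any(cfg$variants %in% c("hybrid", "autoencoder", "deep_embedding",
                            "traditional"))
  cache <- if (needs_features)
    feature_cache(g, seed = child_seed(rep_seed, 11L)) else NULL
  if (!is.null(cfg$detector_models)) {
    cs <- collect_active_constraints(g, gt, cfg$iterations,
                                     cfg$total_budget, cfg$slpa,
                                     cfg$noise_rate,
                                     child_seed(rep_seed, 21L))
    fm <- extract_features(cs, g, cache)
    for (nm in names(cfg$detector_models)) {
      auc <- constraint_noise_auc(cs, g, cfg$detector_models[[nm]],
                                  child_seed(rep_seed, 31L), cache, fm)
      emit("auc_ml", auc["ML"], nm)
      emit("auc_cl", auc["CL"], nm)
    }
  }
  gt_sizes <- vapply(gt, length, 1L)
  for (variant in cfg$variants %||% character(0)) {
    cov <- if (variant == "slpa") {
      run_slpa(g, slpa_params(cfg$slpa$rounds, cfg$slpa$r,
                              child_seed(rep_seed, 41L)))
    } else {
      cleaning <- if (variant == "acslpa_noclean") NULL else
        default_config(scale, variant)
      run_acslpa(g, gt,
                 acslpa_config(iterations = cfg$iterations,
                               total_budget = cfg$total_budget,
                               cleaning = cleaning, slpa = cfg$slpa,
                               noise_rate = cfg$noise_rate,
                               clean = variant != "acslpa_noclean",
                               seed = child_seed(rep_seed, 51L)),
                 cache = cache)$cover
    }
    emit("nmi", overlapping_nmi(cov, gt), variant)
    ks <- ks_two_sample(vapply(cov, length, 1L), gt_sizes)
    emit("ks_D", ks$D, variant)
    emit("ks_p", ks$p, variant)
  }
  do.call(rbind, rows)
}

#' Run a benchmark evaluation suite
#'
#' For every grid cell and replicate seed: generate a benchmark network,
#' optionally evaluate noise-detection AUC of the configured models on
#' actively collected noisy constraints, and optionally run end-to-end
#' variants recording overlapping NMI against the planted cover and the
#' Kolmogorov-Smirnov comparison of community-size distributions. Failures
#' in a cell are recorded and the suite continues.
#'
#' @param cfg A [suite_config()].
#' @return A data frame report with one row per (cell, seed, model, metric);
#'   failed cells appear with metric `"error"`.
#' @export
run_suite <- function(cfg) {
  stopifnot(inherits(cfg, "suite_config"))
  out <- list()
  for (i in seq_len(nrow(cfg$grid))) {
    for (s in seq_len(cfg$seeds_per_cell)) {
      rep_seed <- child_seed(cfg$seed, i * 131L + s)
      cell <- cfg$grid[i, ]
      res <- tryCatch(run_suite_cell(cell, rep_seed, cfg),
                      error = function(e) data.frame(
                        metric = "error", value = NA_real_,
                        model = conditionMessage(e), N = cell$N,
                        mu = cell$mu, On = cell$On, Om = cell$Om,
                        seed = rep_seed))
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Detector-evaluation suite: noise-detection AUC per autoencoder
#'
#' The detached harness for comparing constraint-cleaning models: for every
#' benchmark cell, generate the network, pool constraints over active
#' selection iterations with a perfect oracle, inject label-flip noise at
#' `noise_rate` of the smaller view, extract pair features, and score each
#' requested architecture's reconstruction error against the hidden noise
#' flags. Architectures in `ml_archs` are scored on both views; those in
#' `cl_archs` on the cannot-link view only. The network and its feature
#' cache are shared across the `constraint_seeds` replicate selections.
#'
#' @param grid Benchmark cell data frame (see [benchmark_grid()]).
#' @param ml_archs,cl_archs Character vectors of architecture names
#'   (see [ae_architecture()]); the training regime follows the network
#'   scale.
#' @param constraint_seeds Replicate constraint selections per network.
#' @param iterations,total_budget,slpa Active-selection settings.
#' @param noise_rate Label-flip level (fraction of the smaller view).
#' @param seed Master seed.
#' @return Long data frame with columns `N`, `mu`, `On`, `Om`, `rep`,
#'   `model`, `view`, `auc`.
#' @export
experiment1_suite <- function(grid, ml_archs = c("AE2", "AE2_L1"),
                              cl_archs = character(0),
                              constraint_seeds = 2L, iterations = 10L,
                              total_budget = NULL, slpa = slpa_params(),
                              noise_rate = 0.1, seed = 1L) {
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    bench <- generate_benchmark(benchmark_params(
      N = cell$N, mu = cell$mu, On = cell$On, Om = cell$Om,
      C_min = cell$C_min, C_max = cell$C_max, seed = child_seed(seed, i)))
    scale <- network_scale(bench$network)
    cache <- feature_cache(bench$network, seed = child_seed(seed, i * 7L))
    for (s in seq_len(constraint_seeds)) {
      cs <- collect_active_constraints(bench$network, bench$cover,
                                       iterations = iterations,
                                       total_budget = total_budget,
                                       slpa = slpa, rate = noise_rate,
                                       seed = child_seed(seed, i * 100L + s))
      fm <- extract_features(cs, bench$network, cache)
      emit <- function(model_name, view, auc) {
        rows[[length(rows) + 1L]] <<- data.frame(
          N = cell$N, mu = cell$mu, On = cell$On, Om = cell$Om, rep = s,
          model = model_name, view = view, auc = unname(auc))
      }
      for (nm in ml_archs) {
        auc <- constraint_noise_auc(cs, bench$network,
                                    ae_architecture(nm, scale),
                                    seed = child_seed(seed, i * 31L + s),
                                    cache = cache, fm = fm)
        emit(nm, "ML", auc["ML"])
        emit(nm, "CL", auc["CL"])
      }
      for (nm in setdiff(cl_archs, character(0))) {
        auc <- constraint_noise_auc(cs, bench$network,
                                    ae_architecture(nm, scale),
                                    seed = child_seed(seed, i * 53L + s),
                                    cache = cache, fm = fm, views = "CL")
        emit(nm, "CL", auc["CL"])
      }
    }
  }
  do.call(rbind, rows)
}

#' End-to-end suite: overlapping NMI of detection variants per benchmark cell
#'
#' Runs the requested variants (`"slpa"`, `"acslpa_noclean"`, or a cleaning
#' category name for the full pipeline) on every benchmark cell and records
#' overlapping NMI against the planted cover. The feature cache is shared
#' across variants within a cell.
#'
#' @inheritParams experiment1_suite
#' @param variants Character vector of variants to run.
#' @return Data frame with columns `N`, `mu`, `On`, `Om`, `variant`, `nmi`.
#' @export
experiment3_suite <- function(grid, variants = c("slpa", "hybrid"),
                              iterations = 10L, total_budget = NULL,
                              slpa = slpa_params(), noise_rate = 0.1,
                              seed = 1L) {
  cleaning_variants <- setdiff(variants, c("slpa", "acslpa_noclean"))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    bench <- generate_benchmark(benchmark_params(
      N = cell$N, mu = cell$mu, On = cell$On, Om = cell$Om,
      C_min = cell$C_min, C_max = cell$C_max, seed = child_seed(seed, i)))
    scale <- network_scale(bench$network)
    cache <- if (length(cleaning_variants))
      feature_cache(bench$network, seed = child_seed(seed, i * 7L)) else NULL
    for (variant in variants) {
      cov <- if (variant == "slpa") {
        run_slpa(bench$network,
                 slpa_params(slpa$rounds, slpa$r, child_seed(seed, i * 211L)))
      } else {
        cfg <- acslpa_config(
          iterations = iterations, total_budget = total_budget,
          cleaning = if (variant == "acslpa_noclean") NULL else
            default_config(scale, variant),
          slpa = slpa, noise_rate = noise_rate,
          clean = variant != "acslpa_noclean",
          seed = child_seed(seed, i * 223L))
        run_acslpa(bench$network, bench$cover, cfg, cache = cache)$cover
      }
      rows[[length(rows) + 1L]] <- data.frame(
        N = cell$N, mu = cell$mu, On = cell$On, Om = cell$Om,
        variant = variant, nmi = overlapping_nmi(cov, bench$cover))
    }
  }
  do.call(rbind, rows)
}
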
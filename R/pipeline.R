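#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with the
#' standard analysis parameters (neuropil factor 0.7, SNR gate 0.35,
#' 90% subsampling with Jaccard threshold 0.5 and merge rate 35%,
#' 88 deg/mm retinotopic scale) and desk-scale computational settings
#' (restart and subset counts far below the published 1000; both are
#' plain entries that can be raised).
#'
#' @param ... Named overrides, e.g. `default_config(cluster =
#'   list(k_range = 2:30))` replaces entries of the corresponding block.
#' @return Nested named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = NULL,
    simulate = list(n_types = 24, n_neurons = 1200, snr_target = 2,
                    frame_rate = 4.8, n_repeats = 10,
                    group_split = 10 / 24),
    preprocess = list(snr_threshold = 0.35),
    features = list(n_components = c(MB = 6, LOOM = 6, CHIRP = 20,
                                     COLOR = 8, FDDS = 10),
                    sparsity = 0.5),
    cluster = list(k_range = 2:40, n_restarts = 10, cov_type = "diag",
                   ridge = 1e-6,
                   stability_subsets = 50, stability_fraction = 0.9,
                   stability_restarts = 2,
                   jsc_threshold = 0.5, rate_threshold = 0.35),
    spatial = list(bin_width = 10, r_max = 300, radius = 50,
                   deg_per_mm = 88, n_boot = 200, alpha = 0.01,
                   depth_bins = c(0, 100, 200, 350)),
    retina = list(n_rgc_types = 32, n_boot = 100)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Entries present in the file override the defaults of
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

.validate_config <- function(cfg) {
  problems <- character(0)
  if (!is.null(cfg$cluster$k_min) || !is.null(cfg$cluster$k_max)) {
    if (is.null(cfg$cluster$k_min) || is.null(cfg$cluster$k_max) ||
        cfg$cluster$k_max < cfg$cluster$k_min)
      problems <- c(problems, "cluster$k_max must be >= cluster$k_min")
    else cfg$cluster$k_range <- cfg$cluster$k_min:cfg$cluster$k_max
  }
  kr <- cfg$cluster$k_range
  if (length(kr) == 0 || min(kr) < 1)
    problems <- c(problems, "cluster$k_range must contain counts >= 1")
  if (cfg$simulate$snr_target <= 0)
    problems <- c(problems, "simulate$snr_target must be positive")
  if (cfg$preprocess$snr_threshold < 0)
    problems <- c(problems, "preprocess$snr_threshold must be >= 0")
  if (cfg$cluster$stability_fraction <= 0 ||
      cfg$cluster$stability_fraction >= 1)
    problems <- c(problems, "cluster$stability_fraction must be in (0, 1)")
  if (length(problems) > 0)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg
}

#' Run the full functional-typing pipeline
#'
#' Executes, in order: synthetic-data generation (or loading),
#' SNR gating, index computation, feature construction, GMM clustering
#' with BIC model selection, stability analysis (subsampling Jaccard +
#' co-association) with the merge/flag rule, the type dendrogram, the
#' anatomical statistics, and the retina decomposition. All stages are
#' pure functions of the configuration and its seed: running the same
#' configuration twice yields identical outputs.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @param dataset Optional pre-built `sc_dataset`; when `NULL` one is
#'   simulated from `config$simulate`.
#' @param stages Character vector of stages to run after the dataset is
#'   available (subset of `c("preprocess", "indices", "features",
#'   "cluster", "spatial", "retina")`).
#' @param verbose Print per-stage progress (default TRUE).
#' @return `sc_report`: list with the dataset, index table, features,
#'   BIC curve, final labels, stability report, dendrogram, spatial and
#'   retina results, and a `summary` block (type counts and percentages,
#'   group composition, flags). When `config$out_dir` is set, CSV/JSON/
#'   Newick outputs are written there.
#' @export
run_pipeline <- function(config = default_config(), dataset = NULL,
                         stages = c("preprocess", "indices", "features",
                                    "cluster", "spatial", "retina"),
                         verbose = TRUE) {
  config <- .validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  if (is.null(dataset)) {
    say("simulate: %d neurons from %d archetypes",
        config$simulate$n_neurons, config$simulate$n_types)
    protocols <- build_protocol(config$simulate$frame_rate,
                                config$simulate$n_repeats)
    archetypes <- make_archetypes(config$simulate$n_types,
                                  config$simulate$group_split,
                                  seed = config$seed,
                                  protocols = protocols)
    dataset <- simulate_dataset(archetypes, config$simulate$n_neurons,
                                snr_target = config$simulate$snr_target,
                                seed = config$seed + 1,
                                protocols = protocols)
  }
  out <- list(config = config, dataset = dataset)

  if ("preprocess" %in% stages) {
    n0 <- length(dataset$neurons)
    dataset <- filter_responsive(compute_snr(dataset),
                                 config$preprocess$snr_threshold)
    say("preprocess: %d/%d neurons pass SNR > %.2f",
        length(dataset$neurons), n0, config$preprocess$snr_threshold)
    out$dataset <- dataset
  }

  if ("indices" %in% stages) {
    say("indices: computing per-neuron functional indices")
    out$index_table <- compute_index_table(dataset)
  }

  if ("features" %in% stages) {
    say("features: sparse-PCA feature matrix")
    out$features <- build_features(dataset, out$index_table,
                                   n_components = config$features$n_components,
                                   sparsity = config$features$sparsity)
  }

  if ("cluster" %in% stages) {
    cl <- config$cluster
    say("cluster: BIC scan over K = %d..%d (%d restarts)",
        min(cl$k_range), max(cl$k_range), cl$n_restarts)
    out$bic_curve <- scan_k(out$features, cl$k_range,
                            n_restarts = cl$n_restarts,
                            seed = config$seed + 2,
                            cov_type = cl$cov_type, ridge = cl$ridge)
    model <- out$bic_curve$best_model
    say("cluster: best K = %d; stability over %d subsets",
        out$bic_curve$best_k, cl$stability_subsets)
    out$stability <- jaccard_stability(out$features, model,
                                       fraction = cl$stability_fraction,
                                       n_subsets = cl$stability_subsets,
                                       n_restarts = cl$stability_restarts,
                                       seed = config$seed + 3,
                                       cov_type = cl$cov_type,
                                       ridge = cl$ridge)
    ca <- coassociation(out$stability$label_sets, model$labels)
    out$coassociation <- ca
    mg <- merge_unstable(model$labels, out$stability$jsc,
                         ca$between_cluster_rate,
                         cl$jsc_threshold, cl$rate_threshold)
    out$merge <- mg
    out$labels <- mg$labels
    out$model <- model
    means <- t(vapply(sort(unique(out$labels)), function(k)
      colMeans(out$features$values[out$labels == k, , drop = FALSE]),
      numeric(ncol(out$features$values))))
    if (nrow(means) >= 2) out$dendrogram <- build_dendrogram(means)
  }

  if ("spatial" %in% stages && !is.null(out$labels)) {
    sp <- config$spatial
    say("spatial: density profiles and separation tests")
    psets <- dataset_point_sets(dataset, out$labels)
    types <- sort(unique(out$labels))
    drps <- lapply(types, function(ty)
      average_drp(lapply(psets, drp, type_id = ty,
                         bin_width = sp$bin_width, r_max = sp$r_max)))
    names(drps) <- types
    dep <- vapply(dataset$neurons, `[[`, numeric(1), "depth")
    out$spatial <- list(
      point_sets = psets,
      drp = drps,
      cross_density = if (length(psets) > 0)
        cross_type_density(psets[[1]], radius = sp$radius, types = types),
      depth_composition = depth_composition(dep, out$labels,
                                            sp$depth_bins))
  }

  if ("retina" %in% stages && !is.null(out$labels)) {
    say("retina: linear decomposition onto the RGC bank")
    bank <- simulate_rgc_bank(config$retina$n_rgc_types,
                              seed = config$seed + 4,
                              protocols = dataset$protocols)
    sc_resp <- type_mean_responses(dataset, out$labels)
    fit <- fit_rgc_weights_all(bank, sc_resp)
    out$retina <- list(
      bank = bank, responses = sc_resp, fit = fit,
      group_test = if (!is.null(out$dendrogram))
        group_weight_test(fit$weights, out$dendrogram$groups),
      evr_sc = pca_evr(sc_resp, n_boot = config$retina$n_boot,
                       seed = config$seed + 5),
      evr_rgc = pca_evr(bank, n_boot = config$retina$n_boot,
                        seed = config$seed + 6))
  }

  ## summary ---------------------------------------------------------------
  if (!is.null(out$labels)) {
    tab <- table(out$labels)
    out$summary <- list(
      n_neurons = length(out$labels),
      n_types = length(tab),
      type_counts = as.integer(tab),
      type_percent = as.numeric(tab) / sum(tab) * 100,
      unstable_clusters = out$merge$unstable_flags,
      merged_pairs = out$merge$merged_pairs,
      groups = if (!is.null(out$dendrogram)) out$dendrogram$groups,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  if (!is.null(config$out_dir)) .write_report(out, config$out_dir)
  class(out) <- "sc_report"
  out
}

#' @export
print.sc_report <- function(x, ...) {
  cat("<sc_report>\n")
  if (!is.null(x$summary)) {
    cat(sprintf("  neurons: %d, types: %d\n", x$summary$n_neurons,
                x$summary$n_types))
    cat(sprintf("  type percentages: %s\n",
                paste(sprintf("%.1f", x$summary$type_percent),
                      collapse = " ")))
  }
  invisible(x)
}

.write_report <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  if (!is.null(out$index_table)) w(out$index_table, "indices.csv")
  if (!is.null(out$bic_curve)) w(out$bic_curve$curve, "bic_curve.csv")
  if (!is.null(out$labels))
    w(data.frame(neuron_id = out$features$neuron_ids,
                 cluster = out$labels), "labels.csv")
  if (!is.null(out$stability))
    jsonlite::write_json(
      list(jsc = out$stability$jsc,
           unstable = out$merge$unstable_flags,
           merged = out$merge$merged_pairs),
      file.path(dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(out$dendrogram))
    write_newick(out$dendrogram, file.path(dir, "dendrogram.newick"))
  if (!is.null(out$retina)) {
    utils::write.csv(out$retina$fit$weights,
                     file.path(dir, "rgc_weights.csv"))
    w(data.frame(component = seq_along(out$retina$evr_sc$evr),
                 evr_sc = out$retina$evr_sc$evr,
                 evr_rgc = out$retina$evr_rgc$evr[
                   seq_along(out$retina$evr_sc$evr)]),
      "evr.csv")
  }
  invisible(dir)
}
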
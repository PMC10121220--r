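#' Cluster stability by subsampling Jaccard analysis
#'
#' Refits the mixture on random subsamples of the data (90% by default,
#' using the cluster number selected on the full dataset) and scores each
#' full-data cluster by its mean best-match Jaccard similarity
#' `|intersection| / |union|` with the subset clusters. Neurons absent
#' from a subset are excluded from both sets of each comparison. Clusters
#' with a Jaccard score below 0.5 are conventionally considered unstable
#' (see [merge_unstable()]).
#'
#' @param features `sc_features` or numeric matrix.
#' @param model Full-data `sc_gmm` fit whose clusters are scored.
#' @param fraction Subsample fraction in (0, 1) (default 0.9).
#' @param n_subsets Number of subsamples (default 100; published analyses
#'   use 1000).
#' @param n_restarts Restarts per subset fit (default 2).
#' @param seed Integer seed.
#' @param ... Further arguments to [fit_gmm()].
#' @return `sc_stability`: list with `jsc` (per-cluster scores),
#'   `label_sets` (per-subset assignments, `NA` for absent neurons) and
#'   `subset_indices`.
#' @export
jaccard_stability <- function(features, model, fraction = 0.9,
                              n_subsets = 100, n_restarts = 2, seed = 1,
                              ...) {
  X <- .feature_matrix(features)
  n <- nrow(X)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  m <- round(fraction * n)
  K <- model$K
  if (m < K) stop("subsets smaller than the number of clusters")
  full_labels <- model$labels
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  subset_seeds <- sample.int(2^30, n_subsets)

  label_sets <- vector("list", n_subsets)
  subset_idx <- vector("list", n_subsets)
  jacc <- matrix(0, n_subsets, K)
  for (s in seq_len(n_subsets)) {
    idx <- sort(sample.int(n, m))
    fit <- fit_gmm(X[idx, , drop = FALSE], K, n_restarts = n_restarts,
                   seed = subset_seeds[s], ...)
    lab <- rep(NA_integer_, n)
    lab[idx] <- fit$labels
    label_sets[[s]] <- lab
    subset_idx[[s]] <- idx
    fl <- full_labels[idx]
    for (k in seq_len(K)) {
      in_full <- fl == k
      nf <- sum(in_full)
      if (nf == 0) { jacc[s, k] <- NA; next }
      best <- 0
      for (j in seq_len(K)) {
        in_sub <- fit$labels == j
        inter <- sum(in_full & in_sub)
        uni <- nf + sum(in_sub) - inter
        if (uni > 0 && inter / uni > best) best <- inter / uni
      }
      jacc[s, k] <- best
    }
  }
  structure(list(jsc = colMeans(jacc, na.rm = TRUE),
                 label_sets = label_sets,
                 subset_indices = subset_idx,
                 fraction = fraction, n_subsets = n_subsets),
            class = "sc_stability")
}

#' Co-association matrix across clustering runs
#'
#' For a list of per-neuron cluster assignments (e.g. from the subsampling
#' runs; `NA` marks neurons absent from a run), computes the fraction of
#' runs containing both members of each pair in which the pair shares a
#' cluster. The between-cluster rate is the cluster-wise average of the
#' co-association matrix under a reference partition.
#'
#' @param label_sets List of integer assignment vectors of equal length;
#'   `NA` entries mark absent neurons.
#' @param reference_labels Optional full-data partition used for the
#'   between-cluster rate.
#' @return List with `cam` (neurons x neurons, unit diagonal, `NaN` where
#'   a pair never co-occurred) and, when `reference_labels` is given,
#'   `between_cluster_rate` (K x K).
#' @export
coassociation <- function(label_sets, reference_labels = NULL) {
  if (length(label_sets) == 0) stop("`label_sets` must be non-empty")
  n <- length(label_sets[[1]])
  together <- matrix(0, n, n)
  both <- matrix(0, n, n)
  for (ls in label_sets) {
    if (length(ls) != n) stop("assignment vectors differ in length")
    ip <- which(!is.na(ls))
    eq <- outer(ls[ip], ls[ip], "==")
    together[ip, ip] <- together[ip, ip] + eq
    both[ip, ip] <- both[ip, ip] + 1
  }
  cam <- together / both
  diag(cam) <- 1
  out <- list(cam = cam)
  if (!is.null(reference_labels)) {
    K <- max(reference_labels)
    rate <- matrix(NA_real_, K, K)
    for (a in seq_len(K)) {
      ia <- which(reference_labels == a)
      for (b in seq_len(K)) {
        ib <- which(reference_labels == b)
        block <- cam[ia, ib, drop = FALSE]
        if (a == b) {
          if (length(ia) < 2) next
          vals <- block[lower.tri(block)]
        } else vals <- as.vector(block)
        rate[a, b] <- mean(vals, na.rm = TRUE)
      }
    }
    out$between_cluster_rate <- rate
  }
  out
}

#' Merge or flag unstable clusters
#'
#' Applies the stability rule: a cluster whose Jaccard stability score
#' falls below `jsc_threshold` is merged into the cluster with which it
#' shares the highest between-cluster co-association rate, provided that
#' rate exceeds `rate_threshold` (35% by default); otherwise it is kept
#' and flagged unstable. Unstable clusters are processed in order of
#' increasing stability; rates are not recomputed after a merge. Final
#' labels are relabeled to consecutive integers.
#'
#' @param labels Integer cluster assignment (1..K).
#' @param jsc Per-cluster Jaccard stability scores.
#' @param between_cluster_rate K x K matrix from [coassociation()].
#' @param jsc_threshold Stability threshold (default 0.5).
#' @param rate_threshold Merge rate threshold (default 0.35).
#' @return List with `labels` (relabeled 1..K'), `merged_pairs`
#'   (data.frame of `from`, `to` in original cluster ids),
#'   `unstable_flags` (original ids retained but flagged), and `mapping`
#'   from original to final cluster ids.
#' @export
merge_unstable <- function(labels, jsc, between_cluster_rate,
                           jsc_threshold = 0.5, rate_threshold = 0.35) {
  K <- length(jsc)
  target <- seq_len(K)
  flagged <- integer(0)
  unstable <- order(jsc)[jsc[order(jsc)] < jsc_threshold]
  for (u in unstable) {
    rates <- between_cluster_rate[u, ]
    rates[u] <- -Inf
    partner <- which.max(rates)
    if (is.finite(rates[partner]) && rates[partner] > rate_threshold) {
      target[target == u] <- partner
    } else {
      flagged <- c(flagged, u)
    }
  }
  new_labels <- target[labels]
  kept <- sort(unique(target))
  mapping <- match(target, kept)
  structure(list(
    labels = match(new_labels, kept),
    merged_pairs = if (any(target != seq_len(K)))
      data.frame(from = which(target != seq_len(K)),
                 to = target[target != seq_len(K)])
    else data.frame(from = integer(0), to = integer(0)),
    unstable_flags = flagged,
    mapping = mapping
  ), class = "sc_merge")
}

#' Ward dendrogram over cluster mean responses
#'
#' Agglomerates the cluster means with Ward's minimum-variance linkage on
#' Euclidean distances. The first split of the tree partitions the types
#' into two top-level groups, exported as Group 1 / Group 2 labels.
#'
#' @param cluster_means Numeric matrix, K x feature dims (K >= 2).
#' @return `sc_dendrogram`: list with `hclust`, `leaf_order`, and `groups`
#'   (per-cluster 1/2 top-level group labels; group 1 is the one
#'   containing cluster 1).
#' @export
build_dendrogram <- function(cluster_means) {
  cluster_means <- as.matrix(cluster_means)
  K <- nrow(cluster_means)
  if (K < 2) stop("at least 2 cluster means are required")
  hc <- stats::hclust(stats::dist(cluster_means), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  if (grp[1] != 1) grp <- 3L - grp
  structure(list(hclust = hc, leaf_order = hc$order, groups = grp),
            class = "sc_dendrogram")
}

#' Write a dendrogram in Newick format
#'
#' @param dend `sc_dendrogram` from [build_dendrogram()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(dend, path) {
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
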
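#' Decompose a collicular response into retinal ganglion cell responses
#'
#' Least-squares solution of `argmin_a ||X a - y||^2`, approximating the
#' mean response of one collicular type as a weighted combination of the
#' RGC type responses to the same stimuli (weights are unconstrained;
#' negative weights admit inhibitory interpretations). The prediction
#' error is the normalized residual `||X a - y||^2 / ||y||^2`, zero
#' exactly when the response lies in the span of the RGC bank.
#'
#' @param X Matrix, time samples x RGC types.
#' @param y Response vector (time samples).
#' @return List with `weights`, `prediction_error`, `fitted`, and
#'   `rank_deficient` (TRUE when the minimum-norm solution was used).
#' @export
fit_rgc_weights <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("`X` rows must match length of `y`")
  ny2 <- sum(y^2)
  qrx <- qr(X)
  deficient <- qrx$rank < ncol(X)
  a <- if (deficient) {
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  } else qr.coef(qrx, y)
  a <- drop(a)
  fitted <- drop(X %*% a)
  err <- if (ny2 == 0) NaN else sum((fitted - y)^2) / ny2
  list(weights = a, prediction_error = err, fitted = fitted,
       rank_deficient = deficient)
}

#' Fit RGC weights for every collicular type
#'
#' @param bank RGC bank matrix (RGC types x time), e.g. from
#'   [simulate_rgc_bank()].
#' @param responses Matrix of SC type responses (SC types x time).
#' @param normalize Scale each SC response vector to unit norm before
#'   fitting (default TRUE; recorded in the output).
#' @return List with `weights` (RGC types x SC types),
#'   `prediction_error` per SC type, and `normalized`.
#' @export
fit_rgc_weights_all <- function(bank, responses, normalize = TRUE) {
  X <- t(as.matrix(bank))
  R <- as.matrix(responses)
  W <- matrix(NA_real_, ncol(X), nrow(R),
              dimnames = list(rownames(bank), rownames(R)))
  err <- numeric(nrow(R))
  for (i in seq_len(nrow(R))) {
    y <- R[i, ]
    if (normalize) {
      ny <- sqrt(sum(y^2))
      if (ny > 0) y <- y / ny
    }
    f <- fit_rgc_weights(X, y)
    W[, i] <- f$weights
    err[i] <- f$prediction_error
  }
  list(weights = W, prediction_error = err, normalized = normalize)
}

#' Test which RGC types contribute differentially to the two SC groups
#'
#' For each RGC type, a two-sample t-test of its fitted weights across
#' Group-1 SC types versus Group-2 SC types.
#'
#' @param weights RGC types x SC types weight matrix.
#' @param group_labels Per-SC-type group labels (1 or 2).
#' @param alpha Significance level used for the summary count.
#' @return Data frame with one row per RGC type: mean weight per group,
#'   `direction` (1 or 2, the group with the larger mean), `p_value`
#'   (`NA` when either group has fewer than 2 SC types), `significant`.
#' @export
group_weight_test <- function(weights, group_labels, alpha = 0.05) {
  g1 <- which(group_labels == 1); g2 <- which(group_labels == 2)
  res <- lapply(seq_len(nrow(weights)), function(r) {
    w1 <- weights[r, g1]; w2 <- weights[r, g2]
    if (length(w1) < 2 || length(w2) < 2) {
      return(data.frame(rgc_type = r, mean_g1 = mean(w1), mean_g2 = mean(w2),
                        direction = NA_integer_, p_value = NA_real_,
                        significant = NA))
    }
    tt <- stats::t.test(w1, w2, var.equal = FALSE)
    data.frame(rgc_type = r, mean_g1 = mean(w1), mean_g2 = mean(w2),
               direction = if (mean(w1) >= mean(w2)) 1L else 2L,
               p_value = tt$p.value,
               significant = tt$p.value < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- rownames(weights)
  out
}

#' Explained-variance curve of a response bank
#'
#' Principal component analysis of a types-by-time response matrix (rows
#' are observations): the fraction of variance explained by each
#' component, with bootstrap (row-resampling) standard deviations. A bank
#' whose curve saturates with few components occupies a lower-dimensional
#' response space.
#'
#' @param M Matrix, types x time.
#' @param max_components Number of leading components reported.
#' @param n_boot Bootstrap resamples of the rows (0 disables).
#' @param seed Integer seed for the bootstrap.
#' @return List with `evr` (fractions, sum over all components = 1),
#'   `cumulative`, and `boot_sd` (per reported component).
#' @export
pca_evr <- function(M, max_components = NULL, n_boot = 100, seed = 1) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("at least 2 rows are required")
  evr_of <- function(A) {
    ev <- stats::prcomp(A, center = TRUE, scale. = FALSE)$sdev^2
    ev / sum(ev)
  }
  ev <- evr_of(M)
  mc <- min(max_components %||% length(ev), length(ev))
  boot_sd <- rep(NA_real_, mc)
  if (n_boot > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    B <- matrix(NA_real_, n_boot, mc)
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(M), replace = TRUE)
      eb <- evr_of(M[rows, , drop = FALSE])
      B[b, ] <- eb[seq_len(mc)]
    }
    boot_sd <- apply(B, 2, stats::sd)
  }
  list(evr = ev[seq_len(mc)], cumulative = cumsum(ev)[seq_len(mc)],
       boot_sd = boot_sd, all_evr = ev)
}

#' Mean chirp+color response of each cluster
#'
#' Concatenates each neuron's repeat-mean CHIRP and COLOR responses and
#' averages them within clusters, yielding the SC-type response matrix
#' used for the retina comparison.
#'
#' @param dataset An `sc_dataset`.
#' @param labels Cluster labels per neuron.
#' @return Matrix, clusters x time (CHIRP frames then COLOR frames).
#' @export
type_mean_responses <- function(dataset, labels) {
  traces <- t(vapply(dataset$neurons, function(nr)
    c(rowMeans(nr$trials$CHIRP), rowMeans(nr$trials$COLOR)),
    numeric(dataset$protocols$CHIRP$n_frames +
            dataset$protocols$COLOR$n_frames)))
  ks <- sort(unique(labels))
  out <- t(vapply(ks, function(k)
    colMeans(traces[labels == k, , drop = FALSE]),
    numeric(ncol(traces))))
  rownames(out) <- paste0("SC_", ks)
  out
}
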
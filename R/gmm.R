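#' Bayesian information criterion
#'
#' `BIC = -2 ln L + k ln n`: maximized log-likelihood penalized by the
#' parameter count. Smaller is better.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param n_params Number of free parameters `k`.
#' @param n Number of observations.
#' @return Scalar BIC.
#' @export
bic <- function(log_likelihood, n_params, n) {
  if (n < 1) stop("`n` must be >= 1")
  -2 * log_likelihood + n_params * log(n)
}

.feature_matrix <- function(features) {
  if (inherits(features, "sc_features")) features$values
  else as.matrix(features)
}

#' Fit a Gaussian mixture model by EM with random restarts
#'
#' Expectation-maximization fit of a `K`-component Gaussian mixture to the
#' feature matrix. Each restart starts from kmeans++-seeded centers
#' (briefly refined by Lloyd steps) and runs a capped number of EM
#' iterations; the restart with the highest log-likelihood — equivalently
#' the smallest BIC, since `K` is fixed — is then run to convergence
#' (relative log-likelihood change below `tol`, or `max_iter`
#' iterations). Covariances are full by default with a ridge added to the
#' diagonal; diagonal covariances are available via `cov_type`. Hard
#' labels are maximum-posterior assignments, ties broken toward the
#' lowest cluster index.
#'
#' @param features `sc_features` or numeric matrix (observations x dims).
#' @param K Number of mixture components.
#' @param n_restarts Number of random initializations (default 20; large
#'   published analyses use up to 1000).
#' @param seed Integer seed.
#' @param cov_type `"full"` or `"diag"`.
#' @param ridge Diagonal regularization added to every covariance.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap for the final run.
#' @param restart_iters EM iteration cap per exploratory restart.
#' @return `sc_gmm`: list with `K`, `weights`, `means`, `covariances`,
#'   `log_likelihood`, `n_params`, `bic`, `labels`, `responsibilities`,
#'   `ll_trace`, `converged`, `cov_type`, `seed`.
#' @export
fit_gmm <- function(features, K, n_restarts = 20, seed = 1,
                    cov_type = c("full", "diag"), ridge = 1e-6,
                    tol = 1e-4, max_iter = 500, restart_iters = 15) {
  cov_type <- match.arg(cov_type)
  X <- .feature_matrix(features)
  if (K < 1) stop("`K` must be >= 1")
  if (K >= nrow(X)) stop("`K` must be smaller than the number of neurons")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  res <- .gmm_em_cpp(X, as.integer(K), cov_type == "diag", ridge, tol,
                     as.integer(max_iter), as.integer(n_restarts),
                     as.integer(restart_iters))
  res$K <- K
  res$weights <- drop(res$weights)
  res$labels <- as.integer(res$labels)
  res$cov_type <- cov_type
  res$seed <- seed
  res$bic <- bic(res$log_likelihood, res$n_params, nrow(X))
  class(res) <- "sc_gmm"
  res
}

#' @export
print.sc_gmm <- function(x, ...) {
  cat(sprintf("<sc_gmm: K = %d, logLik = %.1f, BIC = %.1f, %s covariance>\n",
              x$K, x$log_likelihood, x$bic, x$cov_type))
  invisible(x)
}

#' Select the number of clusters by BIC
#'
#' Fits Gaussian mixtures over a range of component counts and records the
#' minimum BIC per count; the reported `best_k` minimizes the curve. The
#' relative curve (`delta_bic = bic - min(bic)`) is included for
#' plotting/export.
#'
#' @param features `sc_features` or numeric matrix.
#' @param k_range Integer vector of component counts (default 2:50).
#' @param n_restarts Restarts per count (passed to [fit_gmm()]).
#' @param seed Integer seed; per-count fits use derived seeds.
#' @param keep_models Keep every fitted model (memory-heavy; default keeps
#'   only the best).
#' @param ... Further arguments to [fit_gmm()].
#' @return `sc_bic_curve`: list with `curve` (data.frame of k, bic,
#'   log_likelihood, n_params, delta_bic), `best_k` and `best_model`.
#' @export
scan_k <- function(features, k_range = 2:50, n_restarts = 20, seed = 1,
                   keep_models = FALSE, ...) {
  if (length(k_range) == 0) stop("`k_range` must be non-empty")
  X <- .feature_matrix(features)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- fit_gmm(X, k_range[i], n_restarts = n_restarts,
                         seed = seed + 7919L * i, ...)
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  curve <- data.frame(
    k = k_range,
    bic = bics,
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    delta_bic = bics - min(bics))
  best <- which.min(bics)
  structure(list(curve = curve,
                 best_k = k_range[best],
                 best_model = fits[[best]],
                 models = if (keep_models) fits else NULL),
            class = "sc_bic_curve")
}

#' @export
print.sc_bic_curve <- function(x, ...) {
  cat(sprintf("<sc_bic_curve: k in [%d, %d], best_k = %d>\n",
              min(x$curve$k), max(x$curve$k), x$best_k))
  invisible(x)
}
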
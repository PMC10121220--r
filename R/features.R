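#' Align a response trace on its extremum
#'
#' Circularly shifts a trace so that its global extremum sits at the
#' canonical center sample. Used to remove the effect of receptive-field
#' position on the timing of moving-bar and looming responses before
#' feature extraction; any circular shift of the same trace aligns to the
#' same output. In `auto` mode the trough is used only when it clearly
#' dominates the peak (`|min| > trough_margin * |max|`): without the
#' margin, alignment of weak or suppressed responses flips between peak
#' and trough from noise alone, splitting one response type into two
#' artificial shape modes.
#'
#' @param trace Numeric vector.
#' @param mode `"auto"`, `"peak"` or `"trough"`.
#' @param trough_margin Dominance factor required to align on the trough
#'   in `auto` mode (default 1.5).
#' @return Shifted trace; a flat trace is returned unchanged with
#'   attribute `flat = TRUE`.
#' @export
align_extremum <- function(trace, mode = c("auto", "peak", "trough"),
                           trough_margin = 1.5) {
  mode <- match.arg(mode)
  n <- length(trace)
  if (n == 0) stop("`trace` must be non-empty")
  if (max(trace) == min(trace)) {
    attr(trace, "flat") <- TRUE
    return(trace)
  }
  i <- switch(mode,
    peak = which.max(trace),
    trough = which.min(trace),
    auto = if (abs(min(trace)) > trough_margin * abs(max(trace)))
             which.min(trace)
           else which.max(trace))
  center <- floor(n / 2) + 1
  shift <- (center - i) %% n
  out <- c(utils::tail(trace, shift), utils::head(trace, n - shift))
  attr(out, "flat") <- FALSE
  out
}

#' Normalize a trace to the unit interval
#'
#' @param trace Numeric vector.
#' @return `(x - min) / (max - min)`; a constant trace maps to all zeros
#'   with attribute `flat = TRUE`.
#' @export
normalize_unit <- function(trace) {
  if (length(trace) == 0) stop("`trace` must be non-empty")
  rng <- range(trace)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(trace))
    attr(out, "flat") <- TRUE
    return(out)
  }
  (trace - rng[1]) / (rng[2] - rng[1])
}

#' Sparse principal component analysis of a response block
#'
#' Factorizes a neurons-by-time response block as `D ~ X F`, where the
#' rows of `F` are sparse, unit-norm temporal components (near-orthonormal,
#' `F F' ~ I`) and `X` holds per-neuron weights. Components are extracted
#' one at a time by thresholded power iteration: power steps toward the
#' leading right singular vector of the deflated residual, interleaved
#' with hard-thresholding that keeps only the largest-magnitude fraction
#' of entries, followed by projection deflation. The weights `X` are the
#' joint least-squares solution given `F`, so reconstruction error is
#' non-increasing in the number of components. Fully deterministic.
#'
#' @param D Numeric matrix, neurons x time.
#' @param n_components Number of components (<= min(dim(D))).
#' @param sparsity Fraction of entries forced to zero in each component
#'   row (default 0.5).
#' @param max_iter Power-iteration cap per component.
#' @return `sc_feature_block`: list with `data`, `components` (F),
#'   `weights` (X), `n_components`, `sparsity` and `reconstruction_error`
#'   (`||D - XF||^2`).
#' @export
sparse_pca <- function(D, n_components, sparsity = 0.5, max_iter = 200) {
  if (!is.matrix(D)) D <- as.matrix(D)
  if (n_components > min(dim(D)))
    stop("`n_components` exceeds the rank bound min(dim(D))")
  if (sparsity < 0 || sparsity >= 1) stop("`sparsity` must be in [0, 1)")
  nt <- ncol(D)
  keep <- max(1L, ceiling((1 - sparsity) * nt))

  R <- D
  Fm <- matrix(0, n_components, nt)
  for (k in seq_len(n_components)) {
    sv <- svd(R, nu = 1, nv = 1)
    v <- sv$v[, 1]
    for (it in seq_len(max_iter)) {
      ord <- order(abs(v), decreasing = TRUE)
      v_new <- v
      v_new[ord[-seq_len(keep)]] <- 0
      nv <- sqrt(sum(v_new^2))
      if (nv == 0) { v_new <- v; nv <- sqrt(sum(v_new^2)) }
      v_new <- v_new / nv
      u <- R %*% v_new
      nu <- sqrt(sum(u^2))
      if (nu == 0) { v <- v_new; break }
      v_next <- drop(crossprod(R, u / nu))
      ord <- order(abs(v_next), decreasing = TRUE)
      v_next[ord[-seq_len(keep)]] <- 0
      nn <- sqrt(sum(v_next^2))
      if (nn == 0) { v <- v_new; break }
      v_next <- v_next / nn
      if (sum(abs(abs(v_next) - abs(v_new))) < 1e-12) { v <- v_next; break }
      v <- v_next
    }
    Fm[k, ] <- v
    R <- R - (R %*% v) %*% t(v)
  }

  G <- Fm %*% t(Fm)
  X <- t(solve(G + diag(1e-12, n_components), Fm %*% t(D)))
  err <- sum((D - X %*% Fm)^2)
  structure(list(data = D, components = Fm, weights = X,
                 n_components = n_components, sparsity = sparsity,
                 reconstruction_error = err),
            class = "sc_feature_block")
}

# fixed-length repeat-mean trace of one stimulus segment
.block_trace <- function(trial_matrix, frames, nf) {
  rowMeans(trial_matrix)[frames[seq_len(nf)]]
}

# centered moving average; denoises repeat-mean traces before alignment
# and [0,1] normalization so the normalizing range is estimated stably
.smooth_trace <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE))
}

#' Build the 54-dimensional feature matrix
#'
#' Assembles the clustering feature space: per-neuron responses to the
#' moving bar (preferred direction only), the looming pair (EBD and RWD
#' concatenated), the chirp, the color flash and the size series are
#' normalized to [0, 1] (bar and looming responses first aligned on their
#' extremum), reduced by sparse PCA with 6/6/20/8/10 components per block,
#' and the resulting 50 weights are concatenated with the four designed
#' indices HI, DSI, OSI and MSI. Every column is then z-scored to mean 0,
#' SD 1. Missing index values are imputed with the column mean before
#' z-scoring.
#'
#' @param dataset An `sc_dataset` (gated by SNR upstream).
#' @param index_table Data frame from [compute_index_table()]; computed on
#'   the fly when `NULL`.
#' @param n_components Named integer vector of components per block.
#' @param sparsity Sparsity fraction passed to [sparse_pca()].
#' @param smooth_frames Width (frames) of the centered moving average
#'   applied to repeat-mean traces before alignment and normalization
#'   (default 3; 1 disables). Index extraction elsewhere is unsmoothed.
#' @return `sc_features`: list with `values` (neurons x 54 matrix),
#'   `column_names`, `neuron_ids` and the per-block `sc_feature_block`s.
#' @export
build_features <- function(dataset, index_table = NULL,
                           n_components = c(MB = 6, LOOM = 6, CHIRP = 20,
                                            COLOR = 8, FDDS = 10),
                           sparsity = 0.5, smooth_frames = 3) {
  prot <- dataset$protocols
  neurons <- dataset$neurons
  n <- length(neurons)
  if (n < max(n_components))
    stop("fewer neurons than the largest per-block component count")
  if (is.null(index_table)) index_table <- compute_index_table(dataset)

  mb_frames <- lapply(seq_len(12), function(d)
    segment_frames(prot$MB, paste0("dir_", d)))
  nf_mb <- min(lengths(mb_frames))

  pref <- index_table$pref_dir
  pref[is.na(pref)] <- 1L

  mb_block <- t(vapply(seq_len(n), function(i) {
    tr <- .block_trace(neurons[[i]]$trials$MB, mb_frames[[pref[i]]], nf_mb)
    normalize_unit(align_extremum(.smooth_trace(tr, smooth_frames)))
  }, numeric(nf_mb)))

  nf_ebd <- prot$EBD$n_frames; nf_rwd <- prot$RWD$n_frames
  loom_block <- t(vapply(seq_len(n), function(i) {
    e <- normalize_unit(align_extremum(
      .smooth_trace(rowMeans(neurons[[i]]$trials$EBD), smooth_frames)))
    w <- normalize_unit(align_extremum(
      .smooth_trace(rowMeans(neurons[[i]]$trials$RWD), smooth_frames)))
    c(e, w)
  }, numeric(nf_ebd + nf_rwd)))

  simple_block <- function(stim) {
    nf <- prot[[stim]]$n_frames
    t(vapply(seq_len(n), function(i)
      normalize_unit(.smooth_trace(rowMeans(neurons[[i]]$trials[[stim]]),
                                   smooth_frames)),
      numeric(nf)))
  }

  blocks <- list(
    MB = sparse_pca(mb_block, n_components[["MB"]], sparsity),
    LOOM = sparse_pca(loom_block, n_components[["LOOM"]], sparsity),
    CHIRP = sparse_pca(simple_block("CHIRP"), n_components[["CHIRP"]],
                       sparsity),
    COLOR = sparse_pca(simple_block("COLOR"), n_components[["COLOR"]],
                       sparsity),
    FDDS = sparse_pca(simple_block("FDDS"), n_components[["FDDS"]], sparsity)
  )

  W <- do.call(cbind, lapply(names(blocks), function(b) {
    w <- blocks[[b]]$weights
    colnames(w) <- paste0(b, "_", seq_len(ncol(w)))
    w
  }))

  designed <- as.matrix(index_table[, c("HI", "DSI", "OSI", "MSI")])
  for (j in seq_len(ncol(designed))) {
    bad <- !is.finite(designed[, j])
    if (any(bad)) designed[bad, j] <- mean(designed[!bad, j])
  }

  V <- cbind(W, designed)
  V <- apply(V, 2, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  })
  rownames(V) <- NULL

  structure(list(values = V,
                 column_names = colnames(V),
                 neuron_ids = vapply(neurons, `[[`, 1, "neuron_id"),
                 blocks = blocks),
            class = "sc_features")
}

#' @export
print.sc_features <- function(x, ...) {
  cat(sprintf("<sc_features: %d neurons x %d features>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
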
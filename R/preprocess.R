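#' Neuropil correction of a raw fluorescence trace
#'
#' Removes out-of-focus neuropil contamination from a somatic fluorescence
#' trace: `F_true = F_raw - r * F_neuropil`, with contamination factor `r`
#' (about 0.7 for typical two-photon setups).
#'
#' @param f_raw Raw somatic fluorescence (a.u.).
#' @param f_neuropil Surrounding neuropil fluorescence, same length.
#' @param r Contamination factor in [0, 1] (default 0.7).
#' @return Corrected fluorescence trace.
#' @export
neuropil_correct <- function(f_raw, f_neuropil, r = 0.7) {
  if (length(f_raw) != length(f_neuropil))
    stop("`f_raw` and `f_neuropil` must have the same length")
  if (!is.numeric(r) || length(r) != 1 || r < 0 || r > 1)
    stop("`r` must lie in [0, 1]")
  f_raw - r * f_neuropil
}

#' Remove slow baseline fluctuations by sliding-percentile subtraction
#'
#' Subtracts from each frame the 8th-percentile value of the trace within a
#' 15 s window centered on that frame. Windows are truncated (not
#' reflected) at the trace edges.
#'
#' @param trace Fluorescence trace.
#' @param frame_rate Frames per second.
#' @param window_s Window length in seconds (default 15).
#' @param percentile Percentile subtracted, in percent (default 8).
#' @return Detrended trace of the same length.
#' @export
detrend_baseline <- function(trace, frame_rate, window_s = 15,
                             percentile = 8) {
  n <- length(trace)
  if (n < 2) stop("`trace` must contain at least 2 samples")
  if (window_s <= 0) stop("`window_s` must be positive")
  half <- max(1L, round(window_s * frame_rate / 2))
  baseline <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(trace[lo:hi], percentile / 100, names = FALSE, type = 7)
  }, numeric(1))
  trace - baseline
}

#' Convert fluorescence to delta-F/F
#'
#' @param f Fluorescence trace.
#' @param f0 Baseline fluorescence: mean intensity during unstimulated
#'   (grey screen) periods. Must be positive; a non-positive baseline
#'   signals a dead or mis-segmented ROI.
#' @return `(f - f0) / f0`.
#' @export
dff <- function(f, f0) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0)
    stop("`f0` must be a positive scalar")
  (f - f0) / f0
}

#' Repeat-reliability signal-to-noise ratio of a trial matrix
#'
#' For a time-by-repeat response matrix `C`, computes
#' `Var_t[ <C>_r ] / < Var_r[C] >_t`: the variance over time of the
#' repeat-averaged response, divided by the time-average of the
#' across-repeat variance. Large values indicate reliable, stimulus-locked
#' responses.
#'
#' @param trial_matrix Numeric matrix, time samples x repeats (both >= 2).
#' @return Scalar SNR. `Inf` when repeats agree exactly on a non-constant
#'   response (zero denominator); `NaN` for a constant matrix (0/0,
#'   treated downstream as failing any threshold).
#' @export
snr <- function(trial_matrix) {
  if (!is.matrix(trial_matrix) || nrow(trial_matrix) < 2 ||
      ncol(trial_matrix) < 2)
    stop("`trial_matrix` must be a matrix with >= 2 rows and >= 2 columns")
  if (!all(is.finite(trial_matrix)))
    stop("`trial_matrix` must be finite")
  num <- stats::var(rowMeans(trial_matrix))
  den <- mean(apply(trial_matrix, 1, stats::var))
  if (den == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  num / den
}

#' Compute per-stimulus SNR for every neuron in a dataset
#'
#' @param dataset An `sc_dataset`.
#' @param stimuli Stimulus ids to score (default: all trial matrices).
#' @return The dataset with each neuron's `snr` field filled with a named
#'   vector of per-stimulus SNR values.
#' @export
compute_snr <- function(dataset, stimuli = NULL) {
  dataset$neurons <- lapply(dataset$neurons, function(nr) {
    ids <- stimuli %||% names(nr$trials)
    nr$snr <- vapply(ids, function(s) snr(nr$trials[[s]]), numeric(1))
    nr
  })
  dataset
}

#' Gate neurons by response reliability
#'
#' Keeps the neurons whose best per-stimulus SNR exceeds `threshold`
#' (default 0.35), i.e. neurons that responded robustly to at least one
#' stimulus. Undefined SNR values (constant trial matrices) fail the
#' threshold. Order is preserved and the operation is idempotent.
#'
#' @param dataset An `sc_dataset` with SNR computed (see [compute_snr()]);
#'   neurons lacking SNR values are scored on the fly.
#' @param threshold SNR threshold (default 0.35).
#' @return The filtered `sc_dataset` (with `labels` subset accordingly).
#' @export
filter_responsive <- function(dataset, threshold = 0.35) {
  if (any(vapply(dataset$neurons, function(nr) is.null(nr$snr), logical(1))))
    dataset <- compute_snr(dataset)
  keep <- vapply(dataset$neurons, function(nr) {
    s <- nr$snr[is.finite(nr$snr) | is.infinite(nr$snr)]
    s <- s[!is.nan(s)]
    length(s) > 0 && max(s) > threshold
  }, logical(1))
  dataset$neurons <- dataset$neurons[keep]
  if (!is.null(dataset$labels)) dataset$labels <- dataset$labels[keep]
  dataset$config$snr_threshold <- threshold
  dataset
}
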
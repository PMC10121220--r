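#' Peak response of a trial matrix in a time window
#'
#' Averages the trial matrix over repeats and extracts the extremum of the
#' mean trace inside a time window. By default the (non-negative) maximum
#' is returned; with `signed = TRUE` the value with the largest absolute
#' magnitude is returned with its sign (used for the response-to-motion
#' readout, which is negative for motion-suppressed neurons).
#'
#' @param trial_matrix Time x repeat matrix.
#' @param window Two-element numeric, time interval in seconds
#'   `[from, to)`.
#' @param frame_rate Frames per second.
#' @param signed Return the signed extremum instead of the maximum.
#' @param rectify Clip the returned maximum at 0 (ignored when `signed`).
#' @return Scalar peak response.
#' @export
peak_response <- function(trial_matrix, window, frame_rate, signed = FALSE,
                          rectify = TRUE) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("`window` must be an increasing time interval")
  tr <- rowMeans(trial_matrix)
  tt <- (seq_along(tr) - 1) / frame_rate
  idx <- which(tt >= window[1] - 1e-9 & tt < window[2] - 1e-9)
  if (length(idx) == 0) stop("`window` lies outside the trace")
  v <- tr[idx]
  if (signed) return(v[which.max(abs(v))])
  if (rectify) max(0, max(v)) else max(v)
}

#' Two-sided selectivity ratio
#'
#' The workhorse contrast of the index battery: `(a - b) / (a + b)`,
#' mapping two non-negative component responses to [-1, 1]. Returns `NaN`
#' when both components are zero (neuron unresponsive to both).
#'
#' @param a,b Non-negative component responses.
#' @return Scalar in [-1, 1], or `NaN` when `a + b == 0`.
#' @export
ratio_index <- function(a, b) {
  s <- a + b
  ifelse(s == 0, NaN, (a - b) / s)
}

#' Vector-sum selectivity of a tuning curve
#'
#' Normalized amplitude of the response-weighted vector sum of the tuning
#' angles at a given angular harmonic: harmonic 1 gives the direction
#' selectivity index, harmonic 2 the orientation selectivity index.
#' Negative responses are clipped to zero before the sum.
#'
#' @param angles Angles in radians.
#' @param responses Peak responses at each angle.
#' @param harmonic Angular harmonic, 1 (direction) or 2 (orientation).
#' @return Scalar in [0, 1]; `NaN` when all responses are zero.
#' @export
vector_selectivity <- function(angles, responses, harmonic = 1) {
  if (length(angles) != length(responses))
    stop("`angles` and `responses` must have the same length")
  if (!harmonic %in% c(1, 2)) stop("`harmonic` must be 1 or 2")
  r <- pmax(responses, 0)
  s <- sum(r)
  if (s == 0) return(NaN)
  Mod(sum(r * exp(1i * harmonic * angles))) / s
}

#' Functional index battery of one neuron
#'
#' Computes the full set of per-neuron functional indices from the trial
#' matrices and the stimulus protocols:
#' \describe{
#'   \item{RtM}{signed extremum of the moving-bar response (negative for
#'     motion-suppressed neurons).}
#'   \item{DSI, OSI}{vector-sum selectivity of the 12-direction tuning
#'     curve at harmonics 1 and 2.}
#'   \item{HI}{habituation: first vs tenth repeat of the expanding black
#'     disc.}
#'   \item{LSI}{expanding black disc vs receding white disc.}
#'   \item{MSI}{moving bar at the preferred direction vs the chirp flash.}
#'   \item{CSI}{white (On) vs black (Off) chirp flash.}
#'   \item{PFSI}{peak vs final response of the preferred flash (transient
#'     vs sustained).}
#'   \item{FSI}{first 3 s vs last 2 s of the frequency-modulation epoch.}
#'   \item{RaFM, RaAM}{response at the sample nearest 1.6 s after the end
#'     of the frequency / amplitude modulation, minus the mean over the
#'     grey segment preceding that modulation.}
#'   \item{BSS}{flashed-disc size with the largest response (ties go to
#'     the smallest size).}
#'   \item{SSI}{2 deg vs 32 deg flashed disc (surround suppression).}
#'   \item{BGI}{blue vs green flash.}
#'   \item{RFS}{receptive-field size (deg^2) from the 2-D Gaussian fit,
#'     `NA` unless the fit explains at least half the variance.}
#' }
#' Component responses of the two-sided ratios are rectified at zero, so
#' those indices stay within [-1, 1]; RtM, RaFM and RaAM are signed.
#' Missing stimuli yield `NA` for the dependent indices only.
#'
#' @param neuron An `sc_neuron` (or any list with `trials` and optionally
#'   `rf_grid`).
#' @param protocols Protocol list from [build_protocol()].
#' @return Named numeric vector of the indices above, with the preferred
#'   direction index (1-12) as attribute `"pref_dir"`.
#' @export
compute_indices <- function(neuron, protocols = build_protocol()) {
  fr <- protocols$MB$frame_rate
  tr <- neuron$trials
  out <- c(RtM = NA_real_, DSI = NA_real_, OSI = NA_real_, HI = NA_real_,
           LSI = NA_real_, MSI = NA_real_, CSI = NA_real_, PFSI = NA_real_,
           FSI = NA_real_, RaFM = NA_real_, RaAM = NA_real_, BSS = NA_real_,
           SSI = NA_real_, BGI = NA_real_, RFS = NA_real_)
  pref_dir <- NA_integer_
  rect_peak <- function(m, frames) max(0, max(rowMeans(m)[frames]))

  ## moving bar -------------------------------------------------------------
  rm_rect <- NA_real_
  if (!is.null(tr$MB)) {
    mtr <- rowMeans(tr$MB)
    out["RtM"] <- mtr[which.max(abs(mtr))]
    dirs <- protocols$MB$directions
    signed_peaks <- vapply(seq_along(dirs), function(d) {
      v <- mtr[segment_frames(protocols$MB, paste0("dir_", d))]
      v[which.max(abs(v))]
    }, numeric(1))
    peaks <- pmax(signed_peaks, 0)
    out["DSI"] <- vector_selectivity(dirs, peaks, 1)
    out["OSI"] <- vector_selectivity(dirs, peaks, 2)
    # preferred direction by response magnitude: for motion-suppressed
    # neurons the rectified peaks are all ~0 and their argmax is noise,
    # whereas the deepest suppression direction is well defined
    pref_dir <- which.max(abs(signed_peaks))
    rm_rect <- peaks[pref_dir]
  }

  ## looming pair -----------------------------------------------------------
  if (!is.null(tr$EBD)) {
    nrep <- ncol(tr$EBD)
    r1 <- max(0, max(tr$EBD[, 1]))
    r10 <- max(0, max(tr$EBD[, nrep]))
    out["HI"] <- ratio_index(r1, r10)
    if (!is.null(tr$RWD)) {
      out["LSI"] <- ratio_index(max(0, max(rowMeans(tr$EBD))),
                                max(0, max(rowMeans(tr$RWD))))
    }
  }

  ## chirp ------------------------------------------------------------------
  if (!is.null(tr$CHIRP)) {
    pr <- protocols$CHIRP
    ctr <- rowMeans(tr$CHIRP)
    rf_all <- max(0, max(ctr))
    if (is.finite(rm_rect)) out["MSI"] <- ratio_index(rm_rect, rf_all)
    w_on <- segment_frames(pr, "white"); w_off <- segment_frames(pr, "black1")
    r_on <- max(0, max(ctr[w_on])); r_off <- max(0, max(ctr[w_off]))
    out["CSI"] <- ratio_index(r_on, r_off)
    w_pref <- if (r_on >= r_off) w_on else w_off
    out["PFSI"] <- ratio_index(max(0, max(ctr[w_pref])),
                               max(0, ctr[w_pref[length(w_pref)]]))
    on <- segment_onsets(pr)
    tt <- protocol_times(pr)
    f_low <- which(tt >= on[["fm"]] - 1e-9 & tt < on[["fm"]] + 3 - 1e-9)
    f_high <- which(tt >= on[["grey2"]] - 2 - 1e-9 & tt < on[["grey2"]] - 1e-9)
    out["FSI"] <- ratio_index(max(0, max(ctr[f_low])),
                              max(0, max(ctr[f_high])))
    base_fm <- mean(ctr[segment_frames(pr, "grey1")])
    base_am <- mean(ctr[segment_frames(pr, "grey2")])
    out["RaFM"] <- ctr[which.min(abs(tt - (on[["grey2"]] + 1.6)))] - base_fm
    out["RaAM"] <- ctr[which.min(abs(tt - (on[["grey3"]] + 1.6)))] - base_am
  }

  ## size tuning ------------------------------------------------------------
  if (!is.null(tr$FDDS)) {
    pr <- protocols$FDDS
    sizes <- pr$disc_sizes
    sp <- vapply(sizes, function(s) {
      rect_peak(tr$FDDS, c(segment_frames(pr, paste0("disc_", s)),
                           segment_frames(pr, paste0("grey_", s))))
    }, numeric(1))
    out["BSS"] <- sizes[which.max(sp)]          # ties -> smallest size
    out["SSI"] <- ratio_index(sp[1], sp[length(sp)])
  }

  ## color ------------------------------------------------------------------
  if (!is.null(tr$COLOR)) {
    pr <- protocols$COLOR
    out["BGI"] <- ratio_index(rect_peak(tr$COLOR, segment_frames(pr, "blue")),
                              rect_peak(tr$COLOR, segment_frames(pr, "green")))
  }

  ## receptive field --------------------------------------------------------
  if (!is.null(neuron$rf_grid)) {
    fit <- fit_rf(neuron$rf_grid)
    if (isTRUE(fit$valid)) out["RFS"] <- fit$rf_size
  }

  attr(out, "pref_dir") <- pref_dir
  out
}

#' Index table for a whole dataset
#'
#' @param dataset An `sc_dataset`.
#' @return Data frame with one row per neuron: `neuron_id`, all indices
#'   from [compute_indices()], and the preferred direction.
#' @export
compute_index_table <- function(dataset) {
  rows <- lapply(dataset$neurons, function(nr) {
    ix <- compute_indices(nr, dataset$protocols)
    data.frame(neuron_id = nr$neuron_id, t(as.numeric(ix)),
               pref_dir = attr(ix, "pref_dir"))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("neuron_id",
                  names(compute_indices(dataset$neurons[[1]],
                                        dataset$protocols)),
                  "pref_dir")
  out
}

#' Relative selectivity of functional types
#'
#' Expresses each type's mean functional property relative to a fixed
#' reference constant per index: `RSI(i, j) = F[i, j] - F[i, ref]`.
#' Default references: 0 for the signed and two-sided indices, 0.15 for
#' DSI and OSI, 0.5 for PFSI, `2^3` deg for the best stimulation size and
#' `10^2.46` deg^2 for the receptive-field size.
#'
#' @param type_means Numeric matrix, indices x types, with rownames naming
#'   the indices.
#' @param references Optional named vector overriding the default
#'   reference constants.
#' @return Object of class `sc_rsi`: list with `values` (same shape as
#'   `type_means`) and `references`.
#' @export
rsi <- function(type_means, references = NULL) {
  defaults <- c(RtM = 0, DSI = 0.15, OSI = 0.15, HI = 0, LSI = 0, MSI = 0,
                CSI = 0, PFSI = 0.5, FSI = 0, RaFM = 0, RaAM = 0,
                BSS = 2^3, SSI = 0, BGI = 0, RFS = 10^2.46)
  refs <- defaults
  if (!is.null(references)) refs[names(references)] <- references
  idx <- rownames(type_means)
  if (is.null(idx)) stop("`type_means` must have index names as rownames")
  unknown <- setdiff(idx, names(refs))
  if (length(unknown) > 0)
    stop("unknown index name(s): ", paste(unknown, collapse = ", "))
  structure(list(values = sweep(type_means, 1, refs[idx], "-"),
                 references = refs[idx]),
            class = "sc_rsi")
}
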
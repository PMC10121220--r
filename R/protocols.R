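#' Stimulus protocols for functional typing
#'
#' Builds the battery of visual stimulus protocols used throughout the
#' pipeline: a full-field moving black bar (MB, 5 deg at 50 deg/s, 12
#' directions), an expanding black disc (EBD) and receding white disc (RWD)
#' looming pair, a sparse-squares receptive-field map (RFMAP, 11 x 11
#' locations), a luminance "chirp" with step flashes plus frequency- and
#' amplitude-modulation epochs, a blue/green color flash (COLOR), and
#' flashing black discs of different sizes (FDDS, 2-32 deg).
#'
#' Segment timings follow the published protocol: the chirp is
#' 3 s black + 3 s white + 3 s black + 3 s grey + 8 s frequency modulation +
#' 3 s grey + 8 s amplitude modulation + 3 s grey + 3 s black (37 s total);
#' each flashed disc is 2 s black + 2 s grey; the color stimulus is
#' 1 s black + 3 s blue + 4 s black + 3 s green + 3 s black.
#'
#' @param frame_rate Imaging frame rate in Hz (default 4.8, the two-photon
#'   scan rate the protocol timings are sampled at).
#' @param n_repeats Number of stimulus repetitions (default 10).
#' @return Named list of `sc_protocol` objects keyed by stimulus id
#'   (`MB`, `EBD`, `RWD`, `RFMAP`, `CHIRP`, `COLOR`, `FDDS`). Each holds the
#'   ordered segment schedule (label, duration, luminance), the frame grid,
#'   and, where relevant, the direction list or disc sizes.
#' @examples
#' prot <- build_protocol()
#' sum(prot$CHIRP$segments$duration)  # 37 s
#' length(prot$MB$directions)         # 12
#' @export
build_protocol <- function(frame_rate = 4.8, n_repeats = 10) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("`frame_rate` must be a positive scalar (Hz)")
  if (!is.numeric(n_repeats) || n_repeats < 1)
    stop("`n_repeats` must be a positive count")

  seg <- function(label, duration, luminance)
    data.frame(label = label, duration = duration, luminance = luminance,
               stringsAsFactors = FALSE)

  directions <- seq(0, 2 * pi, length.out = 13)[1:12]
  mb_seg <- seg(paste0("dir_", seq_len(12)), rep(3, 12), rep("black bar", 12))

  # expansion 2 -> 60 deg at 60 deg/s, hold 0.25 s, grey 2 s (RWD mirrored)
  loom_seg <- seg(c("ramp", "hold", "grey"), c(58 / 60, 0.25, 2),
                  c("disc ramp", "disc static", "grey"))

  chirp_seg <- seg(
    c("black1", "white", "black2", "grey1", "fm", "grey2", "am", "grey3",
      "black3"),
    c(3, 3, 3, 3, 8, 3, 8, 3, 3),
    c("black", "white", "black", "grey", "freq mod 0.5-8 Hz", "grey",
      "amp mod 0-1", "grey", "black"))

  color_seg <- seg(c("black1", "blue", "black2", "green", "black3"),
                   c(1, 3, 4, 3, 3),
                   c("black", "blue", "black", "green", "black"))

  disc_sizes <- c(2, 4, 8, 16, 32)
  fdds_seg <- seg(c(rbind(paste0("disc_", disc_sizes), paste0("grey_", disc_sizes))),
                  rep(2, 10),
                  c(rbind(paste0("black disc ", disc_sizes, " deg"),
                          rep("grey", 5))))

  rf_seg <- seg(c("square", "grey"), c(1, 1), c("black/white square", "grey"))

  mk <- function(id, segments, directions = NULL, disc_sizes = NULL,
                 grid_n = NULL) {
    total <- sum(segments$duration)
    structure(list(
      stimulus_id = id,
      segments = segments,
      frame_rate = frame_rate,
      n_repeats = n_repeats,
      directions = directions,
      disc_sizes = disc_sizes,
      grid_n = grid_n,
      duration = total,
      n_frames = max(2L, round(total * frame_rate))
    ), class = "sc_protocol")
  }

  list(
    MB    = mk("MB", mb_seg, directions = directions),
    EBD   = mk("EBD", loom_seg),
    RWD   = mk("RWD", loom_seg),
    RFMAP = mk("RFMAP", rf_seg, grid_n = 11L),
    CHIRP = mk("CHIRP", chirp_seg),
    COLOR = mk("COLOR", color_seg),
    FDDS  = mk("FDDS", fdds_seg, disc_sizes = disc_sizes)
  )
}

#' @export
print.sc_protocol <- function(x, ...) {
  cat(sprintf("<sc_protocol %s: %.2f s, %d frames @ %.1f Hz, %d repeats>\n",
              x$stimulus_id, x$duration, x$n_frames, x$frame_rate,
              x$n_repeats))
  invisible(x)
}

#' Frame timestamps of a protocol
#'
#' @param protocol An `sc_protocol`.
#' @return Numeric vector of frame-start times in seconds.
#' @export
protocol_times <- function(protocol) {
  (seq_len(protocol$n_frames) - 1) / protocol$frame_rate
}

#' Frame window of a named protocol segment
#'
#' Maps a segment label (or a time interval) to the half-open frame-index
#' window `[from, to)` used for peak extraction. Frames are assigned to the
#' segment whose time interval contains the frame-start timestamp.
#'
#' @param protocol An `sc_protocol`.
#' @param label Segment label, or `NULL` when `from`/`to` are given.
#' @param from,to Time interval in seconds (used when `label` is `NULL`).
#' @return Integer vector of frame indices (1-based).
#' @export
segment_frames <- function(protocol, label = NULL, from = NULL, to = NULL) {
  tt <- protocol_times(protocol)
  if (!is.null(label)) {
    ends <- cumsum(protocol$segments$duration)
    starts <- c(0, ends[-length(ends)])
    i <- match(label, protocol$segments$label)
    if (is.na(i)) stop("unknown segment label: ", label)
    from <- starts[i]; to <- ends[i]
  }
  idx <- which(tt >= from - 1e-9 & tt < to - 1e-9)
  if (length(idx) == 0)
    stop("segment window contains no frames")
  idx
}

#' Segment onset times of a protocol
#' @return Named numeric vector of segment start times (s).
#' @export
segment_onsets <- function(protocol) {
  ends <- cumsum(protocol$segments$duration)
  stats::setNames(c(0, ends[-length(ends)]), protocol$segments$label)
}
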
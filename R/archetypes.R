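#' Archetypal functional cell types for synthetic recordings
#'
#' Generates a bank of archetypal neuron types whose noise-free responses
#' carry designed values of every functional index the pipeline measures
#' (direction/orientation selectivity, habituation, looming/contrast/size/
#' color selectivity, responses after frequency and amplitude modulation,
#' receptive-field geometry). Types are split into two broad groups that
#' mirror the organization seen in collicular recordings: Group 1
#' (subdivided 1a/1b) responds strongly to the localized chirp/flash
#' stimuli and weakly to motion, Group 2 the reverse. At least one type is
#' motion-suppressed (negative moving-bar response) and one prefers the
#' smallest flashed spot.
#'
#' Every stimulus-evoked event in a template is a scaled copy of a single
#' calcium impulse kernel (exponential decay, truncated to a finite
#' support shorter than the gap between measurement windows) placed exactly
#' on the imaging frame grid. Peak responses extracted downstream therefore
#' equal the designed event amplitudes exactly, which makes the designed
#' ratio indices exactly recoverable from noise-free templates.
#'
#' @param n_types Number of archetypes (default 24).
#' @param group_split Fraction of types assigned to Group 1 (default 10/24).
#' @param seed Integer seed; archetype banks are deterministic given
#'   (`n_types`, `group_split`, `seed`).
#' @param protocols Protocol list from [build_protocol()]; used to place
#'   events on the frame grid and to compute achieved index targets.
#' @param tau Calcium kernel decay time constant in seconds (GCaMP6f-like,
#'   default 0.6).
#' @return List of `sc_archetype` objects. Each carries `type_id`, `group`
#'   (`"1a"`, `"1b"` or `"2"`), `target_indices` (named vector of the index
#'   values realized by its noise-free templates), `params` (event
#'   amplitudes and timing), `depth_bias` (probability that a neuron of the
#'   type sits shallower than 100 um) and `patch_scale` (um).
#' @export
make_archetypes <- function(n_types = 24, group_split = 10 / 24, seed = 0,
                            protocols = build_protocol(), tau = 0.6) {
  if (!is.numeric(n_types) || n_types < 2)
    stop("`n_types` must be at least 2")
  n_types <- as.integer(n_types)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  n_g1 <- round(n_types * group_split)
  n_g1 <- max(0L, min(n_types, n_g1))
  groups <- c(rep("1a", ceiling(n_g1 / 2)),
              rep("1b", floor(n_g1 / 2)),
              rep("2", n_types - n_g1))

  # deterministic special roles (cf. motion-suppressed and small-spot types)
  suppressed_ids <- unique(pmin(n_types, c(min(11, n_types), min(19, n_types))))
  small_spot_id <- if (n_types >= 3) 3L else 1L

  # Stratified (Latin-hypercube style) quantiles for the selectivity
  # parameters: a taxonomy of functional types presumes types that are
  # distinct from one another, so each type draws its selectivities from
  # its own stratum of the parameter range rather than independently.
  strat <- function() (sample.int(n_types) - runif(n_types)) / n_types
  Q <- list(csi = strat(), fsi = strat(), bgi = strat(), lsi = strat(),
            hi = strat(), dir = strat(), size = strat(), width = strat(),
            tau = strat(), lat = strat())

  lapply(seq_len(n_types), function(i) {
    .make_one_archetype(i, groups[i], protocols, tau,
                        suppressed = i %in% suppressed_ids,
                        small_spot = i == small_spot_id,
                        q = lapply(Q, `[[`, i))
  })
}

# Truncated, peak-normalized calcium impulse kernel. The 1.25 s support is
# shorter than every gap between measurement windows in the protocols, so
# event responses never bleed into one another's windows.
.kernel_trunc <- 1.25

.calcium_kernel <- function(u, tau = 0.6) {
  ifelse(u >= -1e-9 & u < .kernel_trunc, exp(-pmax(u, 0) / tau), 0)
}

# first frame time >= t on the protocol frame grid
.snap_time <- function(t, protocol) {
  tt <- protocol_times(protocol)
  tt[which(tt >= t - 1e-9)[1]]
}

.make_one_archetype <- function(type_id, group, protocols, tau,
                                suppressed = FALSE, small_spot = FALSE,
                                q = NULL) {
  g1 <- group %in% c("1a", "1b")
  # per-type calcium response dynamics: decay constant and event latencies
  # differ across types, giving each type its own temporal signature
  p <- list()
  qdraw <- function(name, lo, hi) {
    u <- if (is.null(q[[name]])) runif(1) else q[[name]]
    lo + u * (hi - lo)
  }

  ## -- moving bar: tuning curve over 12 directions ------------------------
  dirs <- protocols$MB$directions
  pref <- 1 + floor(qdraw("dir", 0, 1) * length(dirs)) %% length(dirs)
  a1 <- runif(1, 0.1, 1.8)          # 1st-harmonic modulation (direction)
  a2 <- runif(1, 0.1, 1.2)          # 2nd-harmonic modulation (orientation)
  curve <- pmax(0, 1 + a1 * cos(dirs - dirs[pref]) +
                     a2 * cos(2 * (dirs - dirs[pref])))
  curve <- curve / max(curve)
  m_amp <- if (suppressed) -runif(1, 0.4, 1.0)
           else if (g1) runif(1, 0.15, 0.7) else runif(1, 0.8, 2.0)
  p$mb_amps <- m_amp * curve
  p$mb_jitter <- runif(1, 0, 0.8)
  p$pref_dir <- pref
  p$tau <- qdraw("tau", 0.75 * tau, 1.6 * tau)
  tau <- p$tau
  base_lat <- qdraw("lat", 0, 0.5)
  p$lat <- pmin(0.55, pmax(0, base_lat + runif(10, -0.1, 0.1)))
  names(p$lat) <- c("on", "off", "flow", "fhigh", "am", "blue", "green",
                    "fdds", "loom", "spare")

  ## -- flashes / chirp ----------------------------------------------------
  F0 <- if (g1) runif(1, 0.8, 2.0) else runif(1, 0.1, 0.5)
  csi <- qdraw("csi", -0.8, 0.8)
  p$a_on <- F0 * (1 + csi); p$a_off <- F0 * (1 - csi)
  fsi <- qdraw("fsi", -0.8, 0.8)
  fm_base <- F0 * runif(1, 0.3, 1)
  p$a_flow <- fm_base * (1 + fsi); p$a_fhigh <- fm_base * (1 - fsi)
  p$a_am <- F0 * runif(1, 0.2, 1)
  p$rafm <- runif(1, -0.25, 0.5)
  p$raam <- runif(1, -0.25, 0.5)

  ## -- looming pair (EBD habituates across repeats) -----------------------
  hi <- qdraw("hi", -0.1, 0.8)
  L0 <- if (g1) runif(1, 0.4, 1.2) else runif(1, 0.8, 2.2)
  nr <- protocols$EBD$n_repeats
  ratio10 <- (1 - hi) / (1 + hi)
  p$ebd_amps <- L0 * ratio10^(seq(0, 1, length.out = nr))
  lsi <- qdraw("lsi", -0.8, 0.8)
  ebd_mean <- mean(p$ebd_amps)
  p$a_rwd <- ebd_mean * (1 - lsi) / (1 + lsi)

  ## -- size tuning --------------------------------------------------------
  sizes <- protocols$FDDS$disc_sizes
  s_pref <- if (small_spot) 2
            else sizes[1 + floor(qdraw("size", 0, 1) * length(sizes)) %%
                         length(sizes)]
  S0 <- runif(1, 0.5, 2)
  sw <- qdraw("width", 0.8, 1.8)
  p$fdds_amps <- S0 * exp(-(log2(sizes) - log2(s_pref))^2 / (2 * sw^2))

  ## -- color --------------------------------------------------------------
  bgi <- qdraw("bgi", -0.8, 0.8)
  C0 <- F0 * runif(1, 0.4, 1.2)
  p$a_blue <- C0 * (1 + bgi); p$a_green <- C0 * (1 - bgi)

  ## -- receptive field (2-D Gaussian parameters, degrees) -----------------
  p$rf <- c(A = runif(1, 0.5, 1.5), B = runif(1, 3, 10), C = runif(1, 3, 10),
            D = runif(1, 0, pi), E = runif(1, -8, 8), F = runif(1, -8, 8),
            G = 0)

  ## -- achieved index targets (computed from the design) -------------------
  rect <- pmax(p$mb_amps, 0)
  vs <- function(h) {
    if (sum(rect) <= 0) return(NA_real_)
    Mod(sum(rect * exp(1i * h * dirs))) / sum(rect)
  }
  rm_rect <- max(0, p$mb_amps[pref])
  rf_peak <- max(p$a_on, p$a_off, p$a_flow, p$a_fhigh, p$a_am,
                 p$rafm, p$raam, 0)
  # sample offset actually realized for the post-modulation readouts
  on_fm <- segment_onsets(protocols$CHIRP)
  t_rafm <- .nearest_frame_time(on_fm[["grey2"]] + 1.6, protocols$CHIRP)
  t_raam <- .nearest_frame_time(on_fm[["grey3"]] + 1.6, protocols$CHIRP)
  p$t_rafm <- t_rafm; p$t_raam <- t_raam
  # the post-FM readout decays inside the grey segment that serves as the
  # post-AM baseline; fold its analytic tail into the achieved RaAM target
  tt_grey2 <- protocol_times(protocols$CHIRP)[
    segment_frames(protocols$CHIRP, "grey2")]
  raam_baseline <- mean(p$rafm * .calcium_kernel(tt_grey2 - t_rafm, tau))

  targets <- c(
    RtM = m_amp,
    DSI = vs(1), OSI = vs(2),
    HI = hi, LSI = lsi,
    MSI = if (rm_rect + rf_peak > 0) (rm_rect - rf_peak) / (rm_rect + rf_peak)
          else NA_real_,
    CSI = csi,
    PFSI = 1,  # transient archetypes: final flash response decays to zero
    FSI = fsi,
    RaFM = p$rafm, RaAM = p$raam - raam_baseline,
    BSS = s_pref,
    SSI = (p$fdds_amps[1] - p$fdds_amps[length(sizes)]) /
          (p$fdds_amps[1] + p$fdds_amps[length(sizes)]),
    BGI = bgi,
    RFS = pi * 2 * log(10) * p$rf[["B"]] * p$rf[["C"]]
  )

  structure(list(
    type_id = type_id, group = group,
    target_indices = targets, params = p,
    depth_bias = if (g1) runif(1, 0.65, 0.85) else runif(1, 0.1, 0.35),
    patch_scale = 200
  ), class = "sc_archetype")
}

#' @export
print.sc_archetype <- function(x, ...) {
  cat(sprintf("<sc_archetype %d (group %s): DSI %.2f OSI %.2f CSI %.2f BSS %g>\n",
              x$type_id, x$group, x$target_indices[["DSI"]],
              x$target_indices[["OSI"]], x$target_indices[["CSI"]],
              x$target_indices[["BSS"]]))
  invisible(x)
}

# frame time closest to t
.nearest_frame_time <- function(t, protocol) {
  tt <- protocol_times(protocol)
  tt[which.min(abs(tt - t))]
}

#' Noise-free response templates of an archetype
#'
#' Renders the archetype's event design onto the protocol frame grid as
#' per-stimulus template matrices (time x repeat). All stimuli except the
#' expanding black disc are identical across repeats; the EBD amplitude
#' decays geometrically across repeats to realize the designed habituation
#' index.
#'
#' @param arch An `sc_archetype`.
#' @param protocols Protocol list from [build_protocol()].
#' @return Named list of numeric matrices (`n_frames` x `n_repeats`), one
#'   per stimulus id in `MB`, `EBD`, `RWD`, `CHIRP`, `COLOR`, `FDDS`.
#' @export
archetype_templates <- function(arch, protocols = build_protocol()) {
  p <- arch$params
  tau <- p$tau

  render <- function(protocol, times, amps) {
    tt <- protocol_times(protocol)
    y <- numeric(length(tt))
    for (e in seq_along(times)) {
      t0 <- .snap_time(times[e], protocol)
      y <- y + amps[e] * .calcium_kernel(tt - t0, tau)
    }
    y
  }
  rep_mat <- function(y, protocol) {
    matrix(y, nrow = length(y), ncol = protocol$n_repeats)
  }

  ## MB: one bar passage per direction segment
  mb_on <- segment_onsets(protocols$MB)
  mb <- render(protocols$MB, mb_on + p$mb_jitter, p$mb_amps)

  ## EBD / RWD: response at the end of the size ramp; EBD habituates
  loom_t <- 58 / 60 + p$lat[["loom"]]
  ebd_unit <- render(protocols$EBD, loom_t, 1)
  ebd <- outer(ebd_unit, p$ebd_amps)
  rwd <- render(protocols$RWD, loom_t, p$a_rwd)

  ## CHIRP: step flashes, FM onset/offset bursts, post-modulation readouts
  ch_on <- segment_onsets(protocols$CHIRP)
  lat <- p$lat
  chirp <- render(protocols$CHIRP,
                  c(ch_on[["black1"]] + lat[["off"]],
                    ch_on[["white"]] + lat[["on"]],
                    ch_on[["black2"]] + lat[["off"]],
                    ch_on[["fm"]] + lat[["flow"]],
                    ch_on[["grey2"]] - 2 + lat[["fhigh"]],  # last 2 s of FM
                    p$t_rafm,
                    ch_on[["am"]] + lat[["am"]],
                    p$t_raam,
                    ch_on[["black3"]] + lat[["off"]]),
                  c(p$a_off, p$a_on, p$a_off, p$a_flow, p$a_fhigh,
                    p$rafm, p$a_am, p$raam, p$a_off))

  ## COLOR
  co_on <- segment_onsets(protocols$COLOR)
  color <- render(protocols$COLOR,
                  c(co_on[["blue"]] + lat[["blue"]],
                    co_on[["green"]] + lat[["green"]]),
                  c(p$a_blue, p$a_green))

  ## FDDS: one event per disc size
  fd_on <- segment_onsets(protocols$FDDS)
  disc_labels <- paste0("disc_", protocols$FDDS$disc_sizes)
  fdds <- render(protocols$FDDS, fd_on[disc_labels] + lat[["fdds"]],
                 p$fdds_amps)

  list(MB = rep_mat(mb, protocols$MB),
       EBD = ebd,
       RWD = rep_mat(rwd, protocols$RWD),
       CHIRP = rep_mat(chirp, protocols$CHIRP),
       COLOR = rep_mat(color, protocols$COLOR),
       FDDS = rep_mat(fdds, protocols$FDDS))
}

#' Evaluate an archetype's receptive field on the sparse-squares grid
#'
#' @param arch An `sc_archetype`.
#' @param grid_n Grid side length (default 11).
#' @param spacing Square spacing in degrees (default 5).
#' @return `grid_n` x `grid_n` matrix of noise-free peak responses.
#' @export
archetype_rf_grid <- function(arch, grid_n = 11, spacing = 5) {
  half <- (grid_n - 1) / 2
  x <- seq(-half, half) * spacing
  g <- expand.grid(x = x, y = x)
  z <- gauss2d(g$x, g$y, arch$params$rf)
  matrix(z, grid_n, grid_n)
}
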
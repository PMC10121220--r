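#' Simulate a synthetic population recording
#'
#' Draws a population of neurons from a bank of archetypes and renders, for
#' every neuron and stimulus, a trial-by-time response matrix: the
#' archetype's noise-free template scaled by a per-neuron gain, plus
#' independent Gaussian noise calibrated so that the repeat-reliability SNR
#' (variance over time of the repeat-mean divided by the time-mean of the
#' across-repeat variance) matches `snr_target` in expectation.
#'
#' Anatomy emulates the patchy layout of functional types: each type gets
#' one Gaussian patch center per session inside a 600 x 600 um field of
#' view (patch SD 200 um by default), and depths in 0-350 um are biased by
#' group (Group-1 types preferentially shallower than 100 um). Sessions
#' are assigned genotype labels in proportion to the configured genotype
#' mix.
#'
#' @param archetypes List from [make_archetypes()].
#' @param n_neurons Number of neurons (>= number of types).
#' @param snr_target Target repeat-reliability SNR (> 0; default 2).
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   dataset exactly.
#' @param protocols Protocol list from [build_protocol()].
#' @param noise_scale Multiplier on the calibrated noise SD (0 gives
#'   noise-free repeats equal to the templates).
#' @param amp_jitter Log-normal SD of the per-neuron event-amplitude
#'   heterogeneity within a type (default 0.06; 0 makes every neuron an
#'   exact scaled copy of its archetype). Neurons of a type vary most in
#'   the response components their type expresses strongly, so
#'   within-type variability concentrates in type-specific feature
#'   dimensions, as in population recordings.
#' @param patch_sd Patch standard deviation in um (default 200).
#' @param field_um Field-of-view side length in um (default 600).
#' @param neurons_per_session Approximate session size (default 150).
#' @param genotype_mix Named vector of relative genotype frequencies;
#'   defaults to the 490/337/1085/720/485/297 mix of
#'   WT/Vglut2/Vgat/Tac1/Rorb/Ntsr1 mice.
#' @param include_rf_grids Attach a noisy 11 x 11 receptive-field grid per
#'   neuron (default TRUE).
#' @return An `sc_dataset`: list with `neurons` (list of neuron records),
#'   `labels` (ground-truth type per neuron), `archetypes`, `protocols`
#'   and `config`.
#' @export
simulate_dataset <- function(archetypes, n_neurons, snr_target = 2, seed = 1,
                             protocols = build_protocol(),
                             noise_scale = 1, amp_jitter = 0.06,
                             patch_sd = 200, field_um = 600,
                             neurons_per_session = 150,
                             genotype_mix = c(WT = 490, Vglut2 = 337,
                                              Vgat = 1085, Tac1 = 720,
                                              Rorb = 485, Ntsr1 = 297),
                             include_rf_grids = TRUE) {
  n_types <- length(archetypes)
  if (n_neurons < n_types)
    stop("`n_neurons` must be at least the number of archetypes")
  if (!is.numeric(snr_target) || snr_target <= 0)
    stop("`snr_target` must be positive")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  base_templates <- lapply(archetypes, archetype_templates,
                           protocols = protocols)
  stim_ids <- names(base_templates[[1]])

  # mildly unbalanced type proportions
  prop <- rgamma(n_types, shape = 8, rate = 1)
  prop <- prop / sum(prop)
  types <- sample.int(n_types, n_neurons, replace = TRUE, prob = prop)
  # guarantee every type appears
  types[seq_len(n_types)] <- seq_len(n_types)
  types <- types[sample.int(n_neurons)]

  n_sessions <- max(1L, ceiling(n_neurons / neurons_per_session))
  session <- rep(seq_len(n_sessions), length.out = n_neurons)
  session <- sort(session)
  geno_pool <- names(genotype_mix)
  session_geno <- sample(geno_pool, n_sessions, replace = TRUE,
                         prob = genotype_mix / sum(genotype_mix))
  # one patch center per (session, type)
  centers <- array(runif(n_sessions * n_types * 2,
                         0.15 * field_um, 0.85 * field_um),
                   dim = c(n_sessions, n_types, 2))

  neurons <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    ty <- types[i]; se <- session[i]
    arch <- archetypes[[ty]]
    gain <- exp(rnorm(1, 0, 0.15))
    pos <- .draw_patch_position(centers[se, ty, ], patch_sd, field_um)
    depth <- if (runif(1) < arch$depth_bias) runif(1, 0, 100)
             else runif(1, 100, 350)

    templates <- if (amp_jitter > 0)
      archetype_templates(.jitter_archetype(arch, amp_jitter), protocols)
    else base_templates[[ty]]
    trials <- lapply(stim_ids, function(s) {
      tm <- templates[[s]] * gain
      tvar <- stats::var(rowMeans(tm))
      sd_noise <- noise_scale * sqrt(max(tvar, 1e-6) / snr_target)
      tm + matrix(rnorm(length(tm), 0, sd_noise), nrow(tm), ncol(tm))
    })
    names(trials) <- stim_ids

    rf_grid <- NULL
    if (include_rf_grids) {
      g <- archetype_rf_grid(arch) * gain
      rf_grid <- g + matrix(rnorm(length(g), 0, 0.05 * max(abs(g))),
                            nrow(g), ncol(g))
    }

    neurons[[i]] <- structure(list(
      neuron_id = i,
      trials = trials,
      position = pos,
      depth = depth,
      session_id = se,
      mouse_id = paste0("mouse_", session_geno[se], "_",
                        ((se - 1) %% 4) + 1),
      genotype = session_geno[se],
      true_type = ty,
      gain = gain,
      rf_grid = rf_grid,
      snr = NULL
    ), class = "sc_neuron")
  }

  structure(list(
    neurons = neurons,
    labels = types,
    archetypes = archetypes,
    protocols = protocols,
    config = list(n_neurons = n_neurons, snr_target = snr_target,
                  seed = seed, noise_scale = noise_scale,
                  patch_sd = patch_sd, field_um = field_um,
                  neurons_per_session = neurons_per_session)
  ), class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("<sc_dataset: %d neurons, %d types, %d sessions, SNR target %g>\n",
              length(x$neurons), length(x$archetypes),
              length(unique(vapply(x$neurons, `[[`, 1, "session_id"))),
              x$config$snr_target))
  invisible(x)
}

# per-neuron log-normal jitter of the archetype's event amplitudes
.jitter_archetype <- function(arch, sd) {
  p <- arch$params
  jit <- function(x) x * exp(rnorm(length(x), 0, sd))
  p$mb_amps <- jit(p$mb_amps)
  p$ebd_amps <- p$ebd_amps * exp(rnorm(1, 0, sd))
  for (nm in c("a_rwd", "a_on", "a_off", "a_flow", "a_fhigh", "a_am",
               "rafm", "raam", "a_blue", "a_green"))
    p[[nm]] <- jit(p[[nm]])
  p$fdds_amps <- jit(p$fdds_amps)
  out <- arch
  out$params <- p
  out
}

# truncated-Gaussian draw inside the field of view
.draw_patch_position <- function(center, patch_sd, field_um) {
  for (k in 1:50) {
    pos <- rnorm(2, center, patch_sd)
    if (all(pos >= 0 & pos <= field_um)) return(pos)
  }
  pmin(pmax(rnorm(2, center, patch_sd), 0), field_um)
}

#' Simulate a bank of retinal ganglion cell type responses
#'
#' Builds smooth, mutually distinct mean response templates on the
#' concatenated CHIRP + COLOR time base, standing in for a published bank
#' of RGC type responses in the retina-to-colliculus decomposition. Each
#' row is a random smooth curve (a sum of Gaussian bumps and low-frequency
#' sinusoids); rows are generically linearly independent and the function
#' verifies full row rank.
#'
#' @param n_types Number of RGC types (default 32).
#' @param seed Integer seed.
#' @param protocols Protocol list from [build_protocol()].
#' @return Matrix (`n_types` x time samples) with unit-norm rows and
#'   attribute `"time"` holding the concatenated time base in seconds.
#' @export
simulate_rgc_bank <- function(n_types = 32, seed = 0,
                              protocols = build_protocol()) {
  if (!is.numeric(n_types) || n_types < 2)
    stop("`n_types` must be at least 2")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  t1 <- protocol_times(protocols$CHIRP)
  t2 <- protocol_times(protocols$COLOR) + max(t1) + 1 / protocols$CHIRP$frame_rate
  tt <- c(t1, t2)
  nt <- length(tt)
  bank <- matrix(0, n_types, nt)
  for (i in seq_len(n_types)) {
    y <- numeric(nt)
    for (b in seq_len(6)) {
      c0 <- runif(1, 0, max(tt)); w <- runif(1, 0.5, 4)
      y <- y + runif(1, -1, 1) * exp(-(tt - c0)^2 / (2 * w^2))
    }
    f <- runif(2, 0.05, 0.4); ph <- runif(2, 0, 2 * pi)
    y <- y + 0.3 * sin(2 * pi * f[1] * tt + ph[1]) +
             0.2 * sin(2 * pi * f[2] * tt + ph[2])
    bank[i, ] <- y / sqrt(sum(y^2))
  }
  if (qr(bank)$rank < n_types)
    stop("generated RGC bank is rank deficient; use a different seed")
  dimnames(bank) <- list(paste0("RGC_", seq_len(n_types)), NULL)
  attr(bank, "time") <- tt
  bank
}

#' Simulate a raw fluorescence channel for preprocessing tests
#'
#' Converts a known delta-F/F trace into a raw fluorescence trace with
#' out-of-focus neuropil contamination (factor `r`) and slow additive
#' drift, together with the neuropil trace itself, so that the
#' preprocessing chain (neuropil correction, sliding-percentile
#' detrending, delta-F/F) can be tested end to end against ground truth.
#'
#' @param dff Ground-truth delta-F/F trace.
#' @param frame_rate Frames per second.
#' @param f0 Baseline fluorescence (a.u.).
#' @param r Neuropil contamination factor in [0, 1].
#' @param drift_amp Amplitude of the slow drift (a.u.).
#' @param npil_sd SD of neuropil fluctuations (a.u.).
#' @param seed Integer seed.
#' @return List with `f_raw`, `f_neuropil`, `f0`, `dff` and `drift`.
#' @export
simulate_raw_fluorescence <- function(dff, frame_rate = 4.8, f0 = 400,
                                      r = 0.7, drift_amp = 20, npil_sd = 10,
                                      seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- length(dff)
  tt <- (seq_len(n) - 1) / frame_rate
  f_neuropil <- 100 + npil_sd * as.numeric(
    stats::filter(rnorm(n), rep(1 / 8, 8), circular = TRUE)) * sqrt(8)
  drift <- drift_amp * sin(2 * pi * tt / (max(tt) + 1e-9) * 0.8)
  f_true <- f0 * (1 + dff)
  list(f_raw = f_true + r * f_neuropil + drift,
       f_neuropil = f_neuropil, f0 = f0, dff = dff, drift = drift)
}

#' Simulate a labeled Gaussian mixture in feature space
#'
#' Generates the synthetic feature-space mixtures used to validate the
#' clustering stage: `K` clusters with independent standard-normal means
#' per dimension and tight, cluster-specific anisotropic (diagonal)
#' covariances: every cluster is tight in most dimensions but carries
#' larger variance in its own sparse subset of "active" dimensions. This
#' mirrors how functional types live in the z-scored feature space — each
#' type expresses a few feature motifs strongly and variably — and it is
#' the regime in which BIC model selection is informative in high
#' dimension (components differ in covariance shape, not only in mean;
#' a merged component must inflate its determinant across many
#' dimensions, which the BIC penalty cannot absorb). With
#' `overlap_pair = TRUE` the last two clusters share one mean and
#' variance pattern, producing a deliberately unstable split for
#' stability tests.
#'
#' @param K Number of clusters.
#' @param n Number of observations.
#' @param d Dimensionality (default 54, the feature-space size).
#' @param sep SD of the cluster means per dimension (default 1).
#' @param n_active Number of high-variance dimensions per cluster
#'   (default 12).
#' @param sd_active,sd_quiet Within-cluster SD in active / quiet
#'   dimensions (defaults 0.5 and 0.02).
#' @param seed Integer seed.
#' @param overlap_pair Make the last two clusters coincide (default
#'   FALSE).
#' @return List with `X` (n x d matrix) and `labels`.
#' @export
simulate_feature_mixture <- function(K, n, d = 54, sep = 1, n_active = 12,
                                     sd_active = 0.5, sd_quiet = 0.02,
                                     seed = 1, overlap_pair = FALSE) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  mu <- matrix(rnorm(K * d, sd = sep), K, d)
  n_active <- min(n_active, d)
  sd_k <- matrix(sd_quiet, K, d)
  for (k in seq_len(K))
    sd_k[k, sample.int(d, n_active)] <- sd_active
  if (overlap_pair && K >= 2) {
    # one isotropic double-mass cloud: a K-component fit must split it,
    # and the split plane has no preferred orientation across subsamples
    mu[K, ] <- mu[K - 1, ]
    sd_k[K - 1, ] <- sd_k[K, ] <- mean(c(sd_active, sd_quiet))
  }
  lab <- sample.int(K, n, replace = TRUE)
  lab[seq_len(K)] <- seq_len(K)
  X <- mu[lab, ] + matrix(rnorm(n * d), n, d) * sd_k[lab, ]
  list(X = X, labels = lab)
}
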
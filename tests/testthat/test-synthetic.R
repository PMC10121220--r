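test_that("archetype banks are deterministic and span both groups", {
  a1 <- make_archetypes(24, seed = 0)
  a2 <- make_archetypes(24, seed = 0)
  expect_identical(a1, a2)
  groups <- vapply(a1, `[[`, "", "group")
  expect_true(any(groups %in% c("1a", "1b")) && any(groups == "2"))
  # all archetypes in group 1 at the boundary split
  g_all <- make_archetypes(6, group_split = 1, seed = 1)
  expect_true(all(vapply(g_all, `[[`, "", "group") %in% c("1a", "1b")))
  expect_error(make_archetypes(1), "at least 2")
  # at least one motion-suppressed and one small-spot-selective type
  rtm <- vapply(a1, function(a) a$target_indices[["RtM"]], numeric(1))
  bss <- vapply(a1, function(a) a$target_indices[["BSS"]], numeric(1))
  expect_true(any(rtm < 0))
  expect_true(any(bss == 2))
})

test_that("designed direction selectivity is realized by the templates", {
  arch <- fixture_archetypes()
  prot <- fixture_protocols()
  dsis <- vapply(arch, function(a) a$target_indices[["DSI"]], numeric(1))
  top <- order(dsis, decreasing = TRUE)[1:3]
  for (i in top) {
    tpl <- archetype_templates(arch[[i]], prot)
    ix <- compute_indices(list(trials = tpl), prot)
    expect_lt(abs(ix[["DSI"]] - dsis[i]), 0.05)
  }
})

test_that("zero noise reproduces templates; same seed reproduces datasets", {
  arch <- make_archetypes(4, seed = 1)
  ds0 <- simulate_dataset(arch, 8, snr_target = 2, seed = 7, noise_scale = 0,
                          amp_jitter = 0, include_rf_grids = FALSE)
  for (i in seq_along(ds0$neurons)) {
    nr <- ds0$neurons[[i]]
    tpl <- archetype_templates(arch[[nr$true_type]], ds0$protocols)
    for (s in names(tpl))
      expect_equal(nr$trials[[s]], tpl[[s]] * nr$gain, tolerance = 1e-12)
  }
  ds1 <- simulate_dataset(arch, 30, seed = 11)
  ds2 <- simulate_dataset(arch, 30, seed = 11)
  expect_identical(ds1, ds2)
  expect_error(simulate_dataset(arch, 2), "at least")
  expect_error(simulate_dataset(arch, 30, snr_target = 0), "positive")
})

test_that("noise calibration hits the SNR target and is monotone", {
  arch <- make_archetypes(8, seed = 2)
  ds <- simulate_dataset(arch, 200, snr_target = 2, seed = 5,
                         include_rf_grids = FALSE)
  ds <- compute_snr(ds)
  snrs <- unlist(lapply(ds$neurons, `[[`, "snr"))
  med <- median(snrs[is.finite(snrs)])
  expect_gt(med, 1.5)
  expect_lt(med, 2.5)
  # monotone in the target
  med_at <- vapply(c(0.5, 2, 8), function(tg) {
    d <- compute_snr(simulate_dataset(arch, 60, snr_target = tg, seed = 5,
                                      include_rf_grids = FALSE))
    median(unlist(lapply(d$neurons, `[[`, "snr")), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_at) > 0))
})

test_that("simulated anatomy stays in the field with group-biased depths", {
  ds <- fixture_dataset()
  pos <- t(vapply(ds$neurons, `[[`, numeric(2), "position"))
  dep <- vapply(ds$neurons, `[[`, numeric(1), "depth")
  expect_true(all(pos >= 0 & pos <= ds$config$field_um))
  expect_true(all(dep >= 0 & dep <= 350))
  groups <- vapply(ds$archetypes, `[[`, "", "group")
  g1_types <- which(groups %in% c("1a", "1b"))
  shallow <- dep < 100
  frac_g1 <- mean(shallow[ds$labels %in% g1_types])
  frac_g2 <- mean(shallow[!ds$labels %in% g1_types])
  expect_gt(frac_g1, frac_g2)
})

test_that("RGC bank is full-rank, deterministic, and supports exact mixing", {
  bank <- simulate_rgc_bank(32, seed = 0)
  expect_equal(dim(bank)[1], 32)
  expect_equal(qr(bank)$rank, 32)
  expect_identical(bank, simulate_rgc_bank(32, seed = 0))
  expect_error(simulate_rgc_bank(1), "at least 2")
  # a response built inside the span is recovered exactly
  y <- 0.5 * bank[3, ] + 0.5 * bank[7, ]
  fit <- fit_rgc_weights(t(bank), y)
  want <- rep(0, 32); want[c(3, 7)] <- 0.5
  expect_lt(max(abs(fit$weights - want)), 1e-8)
  expect_lt(fit$prediction_error, 1e-10)
})

test_that("raw fluorescence channel round-trips through preprocessing", {
  prot <- fixture_protocols()
  arch <- make_archetypes(4, seed = 3)
  tpl <- archetype_templates(arch[[1]], prot)
  dff_true <- rep(tpl$CHIRP[, 1], 4)
  sim <- simulate_raw_fluorescence(dff_true, frame_rate = 4.8, f0 = 400,
                                   r = 0.7, seed = 2)
  corrected <- neuropil_correct(sim$f_raw, sim$f_neuropil, 0.7)
  detrended <- detrend_baseline(corrected, 4.8)
  # recovered response shape matches the ground-truth delta-F/F
  expect_gt(cor(detrended, dff_true), 0.98)
})

test_that("simulated same-type density is elevated at short range", {
  arch <- make_archetypes(12, seed = 4)
  ds <- simulate_dataset(arch, 900, snr_target = 2, seed = 4,
                         include_rf_grids = FALSE)
  psets <- dataset_point_sets(ds)
  num <- den <- 0
  for (ps in psets) for (ty in unique(ps$labels)) {
    p <- drp(ps, ty, bin_width = 25, r_max = 50)
    if (isTRUE(p$undefined)) next
    lam <- (p$n_reference - 1) / ps$hull_area
    num <- num + sum(p$counts) * p$n_reference
    den <- den + sum(p$areas) * lam * p$n_reference
  }
  # patchy layout: same-type density within 50 um beats the session mean
  expect_gt(num / den, 1.15)
})
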
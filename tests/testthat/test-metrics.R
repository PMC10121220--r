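test_that("ratio index obeys its closed form and antisymmetry", {
  expect_equal(ratio_index(1, 0), 1)
  expect_equal(ratio_index(3, 3), 0)
  expect_equal(ratio_index(3, 1), 0.5)
  expect_true(is.nan(ratio_index(0, 0)))
  for (i in 1:20) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5)
    expect_equal(ratio_index(a, b), -ratio_index(b, a))
    expect_lte(abs(ratio_index(a, b)), 1)
  }
})

test_that("vector selectivity reproduces the analytic cases", {
  ang <- seq(0, 2 * pi, length.out = 13)[1:12]
  one_hot <- c(1, rep(0, 11))
  expect_equal(vector_selectivity(ang, one_hot, 1), 1)
  expect_equal(vector_selectivity(ang, one_hot, 2), 1)
  expect_equal(vector_selectivity(ang, rep(1, 12), 1), 0)
  expect_equal(vector_selectivity(ang, rep(1, 12), 2), 0)
  # equal responses at 0 and 180 degrees only: DSI 0, OSI 1
  anti <- rep(0, 12); anti[c(1, 7)] <- 1
  expect_equal(vector_selectivity(ang, anti, 1), 0)
  expect_equal(vector_selectivity(ang, anti, 2), 1)
  expect_true(is.nan(vector_selectivity(ang, rep(0, 12))))
  expect_error(vector_selectivity(ang, 1:3), "length")
  expect_error(vector_selectivity(ang, rep(1, 12), 3), "1 or 2")
})

test_that("vector selectivity is scale- and rotation-invariant", {
  set.seed(7)
  ang <- seq(0, 2 * pi, length.out = 13)[1:12]
  for (i in 1:10) {
    r <- runif(12)
    rot <- sample(12, 1)
    expect_equal(vector_selectivity(ang, r, 1),
                 vector_selectivity(ang, 3.7 * r, 1))
    expect_equal(vector_selectivity(ang, r, 2),
                 vector_selectivity(ang, r[c(rot:12, seq_len(rot - 1))], 2),
                 tolerance = 1e-12)
  }
})

test_that("peak extraction honors windows, sign and rectification", {
  m <- matrix(c(0.1, 0.8, -0.5, 0.3), 4, 3)
  expect_equal(peak_response(m, c(0, 4 / 4.8), 4.8), 0.8)
  expect_equal(peak_response(m, c(0, 4 / 4.8), 4.8, signed = TRUE), 0.8)
  m2 <- matrix(c(0.1, 0.3, -0.5, 0.2), 4, 2)
  expect_equal(peak_response(m2, c(0, 4 / 4.8), 4.8, signed = TRUE), -0.5)
  expect_error(peak_response(m, c(10, 11), 4.8), "outside")
  expect_error(peak_response(m, c(1, 1), 4.8), "increasing")
})

test_that("noise-free archetypes reproduce every designed index", {
  arch <- fixture_archetypes()
  prot <- fixture_protocols()
  exact <- c("HI", "LSI", "MSI", "CSI", "PFSI", "FSI", "SSI", "BGI")
  for (a in arch) {
    ix <- compute_indices(list(trials = archetype_templates(a, prot)), prot)
    tg <- a$target_indices
    for (nm in exact)
      if (is.finite(tg[[nm]]))
        expect_lt(abs(ix[[nm]] - tg[[nm]]), 1e-12)
    expect_identical(ix[["BSS"]], tg[["BSS"]])
    expect_lt(abs(ix[["RtM"]] - tg[["RtM"]]), 1e-10)
    expect_lt(abs(ix[["RaFM"]] - tg[["RaFM"]]), 1e-10)
    expect_lt(abs(ix[["RaAM"]] - tg[["RaAM"]]), 1e-10)
    if (is.finite(tg[["DSI"]])) {
      expect_lt(abs(ix[["DSI"]] - tg[["DSI"]]), 0.05)
      expect_lt(abs(ix[["OSI"]] - tg[["OSI"]]), 0.05)
    }
  }
})

test_that("boundary archetypes pin the index extremes", {
  prot <- fixture_protocols()
  arch <- fixture_archetypes()
  # motion-suppressed archetype: rectified motion peak 0 -> MSI = -1
  rtm <- vapply(arch, function(a) a$target_indices[["RtM"]], numeric(1))
  sup <- arch[[which(rtm < 0)[1]]]
  ix <- compute_indices(list(trials = archetype_templates(sup, prot)), prot)
  expect_equal(ix[["MSI"]], -1)
  expect_lt(ix[["RtM"]], 0)
  # pure-On chirp: zero Off flash response -> CSI = 1
  tpl <- archetype_templates(arch[[1]], prot)
  tt <- scfunctype:::protocol_times(prot$CHIRP)
  on_only <- 1.5 * scfunctype:::.calcium_kernel(tt - 3.125, 0.6)
  tpl$CHIRP <- matrix(on_only, length(on_only), 10)
  ix2 <- compute_indices(list(trials = tpl), prot)
  expect_equal(ix2[["CSI"]], 1)
  # missing stimulus: dependent indices NA, others still computed
  tpl2 <- archetype_templates(arch[[1]], prot)
  tpl2$COLOR <- NULL
  ix3 <- compute_indices(list(trials = tpl2), prot)
  expect_true(is.na(ix3[["BGI"]]))
  expect_false(is.na(ix3[["DSI"]]))
})

test_that("relative selectivity uses the printed reference constants", {
  idx <- c("RtM", "DSI", "OSI", "HI", "BSS", "RFS")
  tm <- matrix(0, length(idx), 3, dimnames = list(idx, NULL))
  tm["DSI", 1] <- 0.15           # exactly at the reference -> RSI 0
  tm["BSS", ] <- c(2, 8, 32)
  tm["RFS", ] <- 10^2.46
  r <- rsi(tm)
  expect_equal(unname(r$values["DSI", 1]), 0)
  expect_equal(unname(r$references["BSS"]), 8)
  expect_equal(r$values["BSS", ], c(-6, 0, 24))
  expect_equal(unname(r$references["RFS"]), 10^2.46, tolerance = 1e-12)
  expect_equal(r$values["RFS", ], rep(0, 3))
  bad <- matrix(0, 1, 1, dimnames = list("NOPE", NULL))
  expect_error(rsi(bad), "unknown index")
})
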
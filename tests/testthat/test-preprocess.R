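test_that("neuropil correction is exact and validated", {
  expect_equal(neuropil_correct(c(1.7), c(1.0), r = 0.7), 1.0)
  f <- rnorm(50)
  expect_equal(neuropil_correct(f, rep(0, 50), 0.7), f)
  expect_equal(neuropil_correct(f, rnorm(50), 0), f)
  expect_error(neuropil_correct(1:3, 1:4), "length")
  expect_error(neuropil_correct(1:3, 1:3, r = 1.2), "0, 1")
  # linear in the somatic trace
  g <- rnorm(50); np <- rnorm(50)
  expect_equal(neuropil_correct(f + g, np, 0.7) -
                 neuropil_correct(g, np, 0.7) -
                 neuropil_correct(f, np, 0.7),
               -neuropil_correct(rep(0, 50), np, 0.7))
})

test_that("sliding-percentile detrending matches a brute-force oracle", {
  fr <- 4.8
  # constant trace -> exactly zero
  expect_equal(detrend_baseline(rep(3.5, 100), fr), rep(0, 100))
  # brute-force oracle over every window, truncated at the edges
  oracle <- function(x, fr, w = 15, p = 8) {
    half <- max(1, round(w * fr / 2))
    vapply(seq_along(x), function(i)
      x[i] - quantile(x[max(1, i - half):min(length(x), i + half)],
                      p / 100, names = FALSE),
      numeric(1))
  }
  ramp <- seq(0, 10, length.out = 200)
  expect_equal(detrend_baseline(ramp, fr), oracle(ramp, fr))
  # interior of a ramp detrends to a positive constant
  interior <- detrend_baseline(ramp, fr)[60:140]
  expect_true(all(interior > 0))
  expect_lt(diff(range(interior)), 1e-10)
  # impulse on a flat baseline survives, baseline goes to ~0
  x <- rep(1, 150); x[75] <- 9
  d <- detrend_baseline(x, fr)
  expect_equal(d, oracle(x, fr))
  expect_equal(d[75], 8)
  expect_true(all(abs(d[-75]) < 1e-12))
  expect_error(detrend_baseline(numeric(0), fr), "at least 2")
})

test_that("delta-F/F is linear with a guarded baseline", {
  expect_equal(dff(rep(2, 10), 2), rep(0, 10))
  expect_equal(dff(4, 2), 1.0)
  expect_error(dff(1:5, 0), "positive")
  expect_error(dff(1:5, -3), "positive")
  f <- rnorm(20, 10); g <- rnorm(20)
  expect_equal(dff(f + g, 2), dff(f, 2) + g / 2)
})

test_that("SNR matches its sampling theory and degenerate contracts", {
  # identical non-constant repeats: zero denominator -> Inf
  m <- matrix(rep(sin(1:20), 5), 20, 5)
  expect_identical(snr(m), Inf)
  # constant matrix: 0/0 -> NaN
  expect_true(is.nan(snr(matrix(2, 10, 4))))
  expect_error(snr(matrix(1:4, 1, 4)), ">= 2")
  expect_error(snr(matrix(1:4, 4, 1)), ">= 2")
  # pure iid noise with 10 repeats: numerator ~ sigma^2/10, denominator ~
  # sigma^2, so the mean SNR over many matrices is ~0.1
  set.seed(42)
  vals <- replicate(1000, snr(matrix(rnorm(40 * 10), 40, 10)))
  expect_lt(abs(mean(vals) - 0.1), 0.02)
  # invariant to adding a constant
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(snr(x), snr(x + 7))
})

test_that("responsiveness gate keeps exactly the reliable neurons", {
  ds <- snr_stub_dataset(c(0.2, 0.36, 0.5))
  kept <- filter_responsive(ds, 0.35)
  expect_equal(vapply(kept$neurons, `[[`, 1, "neuron_id"), c(2, 3))
  # all below threshold -> empty
  expect_length(filter_responsive(snr_stub_dataset(c(0.1, 0.2)), 0.35)$neurons,
                0)
  # zero threshold keeps all positive
  expect_length(filter_responsive(snr_stub_dataset(c(0.01, 1)), 0)$neurons, 2)
  # NaN-flagged undefined SNR fails the gate
  expect_length(filter_responsive(snr_stub_dataset(c(NaN, 0.5)), 0.35)$neurons,
                1)
  # idempotent
  once <- filter_responsive(ds, 0.35)
  twice <- filter_responsive(once, 0.35)
  expect_equal(vapply(twice$neurons, `[[`, 1, "neuron_id"),
               vapply(once$neurons, `[[`, 1, "neuron_id"))
})
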
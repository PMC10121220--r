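# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

.fx <- new.env()

fixture_protocols <- function() {
  if (is.null(.fx$protocols)) .fx$protocols <- build_protocol()
  .fx$protocols
}

fixture_archetypes <- function() {
  if (is.null(.fx$arch))
    .fx$arch <- make_archetypes(24, seed = 0, protocols = fixture_protocols())
  .fx$arch
}

# small noisy population used by feature/pipeline tests
fixture_dataset <- function() {
  if (is.null(.fx$ds)) {
    arch <- make_archetypes(8, seed = 2, protocols = fixture_protocols())
    .fx$ds <- simulate_dataset(arch, 240, snr_target = 3, seed = 3,
                               protocols = fixture_protocols())
  }
  .fx$ds
}

# a minimal hand-built dataset with preset SNR values
snr_stub_dataset <- function(snrs) {
  neurons <- lapply(seq_along(snrs), function(i)
    structure(list(neuron_id = i, trials = list(),
                   snr = c(CHIRP = snrs[i])), class = "sc_neuron"))
  structure(list(neurons = neurons, labels = seq_along(snrs),
                 protocols = fixture_protocols(), config = list()),
            class = "sc_dataset")
}

expect_perm_equal <- function(a, b, tol = 1e-8) {
  expect_equal(sort(a), sort(b), tolerance = tol)
}
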